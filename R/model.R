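#' Construct a bilinear dynamic causal model
#'
#' A deterministic bilinear DCM describes the hidden neuronal activity
#' `z(t)` of `m` brain regions driven by experimental inputs `u(t)`:
#' \deqn{\dot z = (A + \sum_i B^{(i)} u_i) z + C u}
#' `A` holds the fixed (average) connection strengths in Hz, each `B[[i]]`
#' the change in coupling induced by modulatory input `i`, and `C` the
#' strengths with which driving inputs enter regions.  Structure masks are
#' binary; a parameter is free exactly where its mask entry is 1.  The
#' diagonal of the `A` mask is always 1: self-connections are part of every
#' DCM and are conventionally negative (inhibitory, preventing run-away
#' excitation).
#'
#' @param a_mask,a_values `m x m` binary structure mask and values (Hz) of
#'   the fixed connectivity matrix `A`.  Rows index target regions, columns
#'   source regions.
#' @param c_mask,c_values `m x n_inputs` mask and values of the driving
#'   input matrix `C`.
#' @param b_masks,b_values optional lists (one `m x m` mask/value pair per
#'   input, in input order) of modulatory matrices `B`.  Missing entries or
#'   `NULL` elements mean no modulation by that input.
#' @param region_names,input_names character labels; defaults are generated.
#' @return An object of class `dcm_model`.
#' @examples
#' m <- dcm_model(a_mask = matrix(c(1, 1, 1, 1), 2),
#'                a_values = matrix(c(-0.5, 0.3, 0.2, -0.5), 2),
#'                c_mask = matrix(c(1, 0), 2),
#'                c_values = matrix(c(0.8, 0), 2))
#' n_params(m)
#' @export
dcm_model <- function(a_mask, a_values, c_mask, c_values,
                      b_masks = NULL, b_values = NULL,
                      region_names = NULL, input_names = NULL) {
  a_mask <- as.matrix(a_mask); a_values <- as.matrix(a_values)
  c_mask <- as.matrix(c_mask); c_values <- as.matrix(c_values)
  m <- nrow(a_mask)
  if (m < 1L || ncol(a_mask) != m)
    stop("matrix A must be square with at least one region")
  if (!identical(dim(a_values), dim(a_mask)))
    stop("matrix A: mask and values have different dimensions")
  if (nrow(c_mask) != m)
    stop("matrix C: row count must equal the number of regions")
  if (!identical(dim(c_values), dim(c_mask)))
    stop("matrix C: mask and values have different dimensions")
  n_inputs <- ncol(c_mask)

  if (is.null(region_names)) region_names <- sprintf("R%d", seq_len(m))
  if (is.null(input_names)) input_names <- sprintf("u%d", seq_len(n_inputs))
  if (length(region_names) != m) stop("region_names has wrong length")
  if (length(input_names) != n_inputs) stop("input_names has wrong length")

  empty <- matrix(0, m, m)
  bm <- bv <- rep(list(empty), n_inputs)
  if (!is.null(b_masks)) {
    if (length(b_masks) > n_inputs)
      stop("matrix B: more modulatory matrices than inputs")
    for (i in seq_along(b_masks)) {
      if (is.null(b_masks[[i]])) next
      bmi <- as.matrix(b_masks[[i]])
      bvi <- if (!is.null(b_values) && !is.null(b_values[[i]]))
        as.matrix(b_values[[i]]) else matrix(0, m, m)
      if (!identical(dim(bmi), c(m, m)) || !identical(dim(bvi), c(m, m)))
        stop(sprintf("matrix B(%d): dimensions must be %d x %d", i, m, m))
      bm[[i]] <- bmi; bv[[i]] <- bvi
    }
  }

  .check_mask <- function(mask, values, what) {
    if (!all(mask %in% c(0, 1)))
      stop(sprintf("matrix %s: mask must be binary", what))
    if (any(values[mask == 0] != 0))
      stop(sprintf("matrix %s: nonzero value outside the structure mask", what))
  }
  diag(a_mask) <- 1  # self-connections are always present
  .check_mask(a_mask, a_values, "A")
  .check_mask(c_mask, c_values, "C")
  for (i in seq_len(n_inputs)) .check_mask(bm[[i]], bv[[i]], sprintf("B(%d)", i))

  out <- structure(list(region_names = region_names,
                        input_names = input_names,
                        a_mask = a_mask, a_values = a_values,
                        b_masks = bm, b_values = bv,
                        c_mask = c_mask, c_values = c_values),
                   class = "dcm_model")
  out$map <- .build_map(out)
  out
}

# Fixed packing order: A row-major, then each B(i) in input order
# row-major, then C row-major.  Built once per model; all pack/unpack
# operations index through it.
.build_map <- function(model) {
  rowmajor <- function(mask) {
    w <- which(t(mask) == 1, arr.ind = TRUE)  # column-major of the
    cbind(row = w[, 2], col = w[, 1])         # transpose = row-major
  }
  blocks <- list()
  a <- rowmajor(model$a_mask)
  if (nrow(a)) blocks[[1]] <- data.frame(
    matrix = "A", input = NA_integer_, row = a[, 1], col = a[, 2],
    label = sprintf("A:%s->%s", model$region_names[a[, 2]],
                    model$region_names[a[, 1]]))
  for (i in seq_along(model$b_masks)) {
    b <- rowmajor(model$b_masks[[i]])
    if (nrow(b)) blocks[[length(blocks) + 1L]] <- data.frame(
      matrix = "B", input = i, row = b[, 1], col = b[, 2],
      label = sprintf("B(%s):%s->%s", model$input_names[i],
                      model$region_names[b[, 2]],
                      model$region_names[b[, 1]]))
  }
  cc <- rowmajor(model$c_mask)
  if (nrow(cc)) blocks[[length(blocks) + 1L]] <- data.frame(
    matrix = "C", input = NA_integer_, row = cc[, 1], col = cc[, 2],
    label = sprintf("C:%s->%s", model$input_names[cc[, 2]],
                    model$region_names[cc[, 1]]))
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' @export
print.dcm_model <- function(x, ...) {
  cat(sprintf("Bilinear DCM: %d region(s) [%s], %d input(s) [%s], %d free parameter(s)\n",
              length(x$region_names), paste(x$region_names, collapse = ", "),
              length(x$input_names), paste(x$input_names, collapse = ", "),
              n_params(x)))
  invisible(x)
}

#' Number of free parameters of a model
#' @param model a [dcm_model()].
#' @return Integer count of nonzero mask entries across `A`, `B`, `C`.
#' @export
n_params <- function(model) {
  sum(model$a_mask) + sum(vapply(model$b_masks, sum, 0)) + sum(model$c_mask)
}

#' Pack model parameters into an ordered vector
#'
#' The free parameters are packed in a fixed order: `A` entries row-major,
#' then each `B(i)` in input order row-major, then `C` row-major.  The
#' returned vector carries an `index_map` attribute (matrix, input, row,
#' column, label) so that `unpack_params()` is its exact inverse.
#'
#' @param model a [dcm_model()].
#' @return Named numeric vector of class `dcm_params`.
#' @export
pack_params <- function(model) {
  map <- param_map(model)
  vals <- numeric(nrow(map))
  ia <- map$matrix == "A"
  vals[ia] <- model$a_values[cbind(map$row[ia], map$col[ia])]
  for (i in seq_along(model$b_masks)) {
    ib <- map$matrix == "B" & !is.na(map$input) & map$input == i
    if (any(ib)) vals[ib] <- model$b_values[[i]][cbind(map$row[ib], map$col[ib])]
  }
  ic <- map$matrix == "C"
  vals[ic] <- model$c_values[cbind(map$row[ic], map$col[ic])]
  structure(setNames(vals, map$label), index_map = map, class = "dcm_params")
}

#' Write a parameter vector back into a model
#' @param model a [dcm_model()].
#' @param theta numeric vector in packing order (see [pack_params()]).
#' @return The model with updated `a_values`, `b_values`, `c_values`.
#' @export
unpack_params <- function(model, theta) {
  map <- param_map(model)
  if (length(theta) != nrow(map))
    stop(sprintf("parameter vector has length %d, model has %d free parameters",
                 length(theta), nrow(map)))
  if (any(!is.finite(theta))) stop("parameter vector contains non-finite values")
  ia <- map$matrix == "A"
  model$a_values[cbind(map$row[ia], map$col[ia])] <- theta[ia]
  for (i in seq_along(model$b_masks)) {
    ib <- map$matrix == "B" & !is.na(map$input) & map$input == i
    if (any(ib))
      model$b_values[[i]][cbind(map$row[ib], map$col[ib])] <- theta[ib]
  }
  ic <- map$matrix == "C"
  model$c_values[cbind(map$row[ic], map$col[ic])] <- theta[ic]
  model
}

#' Index map of the free parameters
#' @param model a [dcm_model()].
#' @return A data frame with columns matrix, input, row, col, label.
#' @export
param_map <- function(model) {
  if (!is.null(model$map)) model$map else .build_map(model)
}

#' Bilinear neuronal state derivative
#'
#' Evaluates `dz/dt = (A + sum_i B(i) u_i) z + C u` at one time point.
#'
#' @param z numeric state vector (one activity per region).
#' @param u numeric input vector (one value per input).
#' @param model a [dcm_model()].
#' @return The state derivative in Hz.
#' @export
neuronal_derivative <- function(z, u, model) {
  m <- nrow(model$a_values)
  if (length(z) != m)
    stop(sprintf("matrix A is %d x %d but state has length %d", m, m, length(z)))
  if (length(u) != ncol(model$c_values))
    stop(sprintf("matrix C has %d input column(s) but input has length %d",
                 ncol(model$c_values), length(u)))
  if (any(!is.finite(z)) || any(!is.finite(u)))
    stop("state and input must be finite")
  M <- model$a_values
  for (i in seq_along(u))
    if (u[i] != 0) M <- M + model$b_values[[i]] * u[i]
  drop(M %*% z + model$c_values %*% u)
}
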