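#' Integrate the neuronal state equation
#'
#' Solves the bilinear ODE piecewise on the microtime grid
#' (`ts = tr / n_slices`): the time series is split into bins wherever an
#' input changes, and within each bin the frozen linear system
#' `M = A + sum_i B(i) u_i` is propagated exactly by the matrix exponential
#' of the augmented affine system.  Bin boundaries coincide exactly with
#' input change points and microtime samples.
#'
#' Divergence (`|z| > 1e6` or non-finite states) is reported through the
#' `diverged` flag, never raised: beyond the divergence point the
#' trajectory is truncated (NA).
#'
#' @param model a [dcm_model()].
#' @param design a [design_spec()].
#' @param init initial state; default 0 in every region (resting
#'   baseline).
#' @return An object of class `dcm_trajectory`: `times` (microtime grid,
#'   s), `z` (`m x n_timepoints` states), `diverged`.
#' @export
integrate_neuronal <- function(model, design, init = NULL) {
  m <- nrow(model$a_values)
  if (is.null(init)) init <- rep(0, m)
  if (length(init) != m || any(!is.finite(init)))
    stop("init must be a finite vector with one entry per region")
  seg <- design_segments(design, length(model$input_names))
  res <- .sim_neuronal_cpp(model$a_values, .b_cube(model), model$c_values,
                           seg$prop_u, seg$prop_dt, seg$seg_prop,
                           seg$seg_rec, seg$n_grid, init)
  structure(list(times = seg$times, z = res$z, diverged = res$diverged,
                 step = design$microtime_step), class = "dcm_trajectory")
}

.b_cube <- function(model) {
  m <- nrow(model$a_values); n <- length(model$b_values)
  if (n == 0) return(array(numeric(0), dim = c(m, m, 0)))
  array(unlist(model$b_values, use.names = FALSE), dim = c(m, m, n))
}

#' Convolve a neuronal trajectory into BOLD observations
#'
#' Per region, the neuronal activity is convolved causally with the
#' sampled HRF kernel (scaled by the microtime step, approximating the
#' convolution integral) and downsampled to one observation per TR at the
#' configured slice reference (`sample_offset`, default the first
#' microtime bin of each TR period).  The map is linear in the trajectory.
#'
#' @param traj a [integrate_neuronal()] trajectory.
#' @param kernel an [canonical_hrf()] kernel sampled at the trajectory's
#'   microtime step.
#' @param design the [design_spec()] used to produce `traj`.
#' @return `m x n_volumes` observation matrix; all-NA with attribute
#'   `diverged = TRUE` if the trajectory diverged.
#' @export
observe_bold <- function(traj, kernel, design) {
  if (abs(kernel$step - design$microtime_step) > 1e-9)
    stop(sprintf("kernel step (%g s) does not match the microtime step (%g s)",
                 kernel$step, design$microtime_step))
  if (ncol(traj$z) != design$n_slices * design$n_volumes)
    stop("trajectory length does not match the design's microtime grid")
  if (isTRUE(traj$diverged)) {
    y <- matrix(NA_real_, nrow(traj$z), design$n_volumes)
    attr(y, "diverged") <- TRUE
    return(y)
  }
  y <- .bold_from_neuronal_cpp(traj$z, kernel$values, design$microtime_step,
                               design$n_slices, design$n_volumes,
                               design$sample_offset)
  rownames(y) <- rownames(traj$z)
  y
}

# Fast path used inside estimation and profiling: precompute everything
# that does not depend on parameter values once, then evaluate the
# model -> BOLD map with a single call into the compiled core.
.sim_context <- function(model, design, kernel = NULL) {
  if (is.null(kernel)) kernel <- canonical_hrf(design$microtime_step)
  if (abs(kernel$step - design$microtime_step) > 1e-9)
    stop("kernel step does not match the design's microtime step")
  seg <- design_segments(design, length(model$input_names))
  list(seg = seg, kernel = kernel, design = design,
       m = nrow(model$a_values), init = rep(0, nrow(model$a_values)))
}

.sim_bold_ctx <- function(ctx, a_values, b_cube, c_values) {
  seg <- ctx$seg
  res <- .sim_neuronal_cpp(a_values, b_cube, c_values, seg$prop_u,
                           seg$prop_dt, seg$seg_prop, seg$seg_rec,
                           seg$n_grid, ctx$init)
  if (res$diverged) return(list(y = NULL, diverged = TRUE))
  d <- ctx$design
  list(y = .bold_from_neuronal_cpp(res$z, ctx$kernel$values,
                                   d$microtime_step, d$n_slices,
                                   d$n_volumes, d$sample_offset),
       diverged = FALSE)
}
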