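#' Simulate the noise-free BOLD response
#'
#' Composition of [integrate_neuronal()] and [observe_bold()]: the
#' deterministic neuronal model is integrated on the microtime grid and
#' convolved with the canonical HRF to give the deterministic BOLD
#' response, one row per region, one column per acquired volume.
#'
#' @param model a [dcm_model()].
#' @param design a [design_spec()].
#' @param params optional parameter vector (packing order of
#'   [pack_params()]) written into the model before simulating.
#' @param kernel optional HRF kernel; default [canonical_hrf()] at the
#'   design's microtime step.
#' @return `m x n_volumes` matrix; if the trajectory diverged, all-NA with
#'   attribute `diverged = TRUE`.
#' @export
simulate_clean <- function(model, design, params = NULL, kernel = NULL) {
  if (!is.null(params)) model <- unpack_params(model, as.numeric(params))
  if (is.null(kernel)) kernel <- canonical_hrf(design$microtime_step)
  traj <- integrate_neuronal(model, design)
  y <- observe_bold(traj, kernel, design)
  rownames(y) <- model$region_names
  y
}

#' Add SNR-calibrated Gaussian noise to a clean BOLD signal
#'
#' Per region `i`, the noise standard deviation is
#' `sigma_i = sd(y_clean_i) / snr` (SNR as SD-ratio, the fMRI convention)
#' and independent `N(0, sigma_i)` draws are added to every sample.
#'
#' @param y_clean `m x n_volumes` noise-free BOLD matrix.
#' @param snr target signal-to-noise ratio (> 0, or `Inf` for noise-free).
#' @param seed integer RNG seed; identical seed and input reproduce the
#'   noise bit-exactly.
#' @return List with `y_obs` and `sigma` (per-region SD; 0 with attribute
#'   `noise_free = TRUE` when `snr = Inf`).
#' @export
add_noise <- function(y_clean, snr, seed) {
  if (isTRUE(attr(y_clean, "diverged")))
    stop("refusing to add noise to a diverged simulation")
  if (!is.numeric(snr) || snr <= 0) stop("snr must be > 0 (or Inf)")
  if (is.infinite(snr)) {
    sigma <- rep(0, nrow(y_clean))
    attr(sigma, "noise_free") <- TRUE
    return(list(y_obs = y_clean, sigma = sigma))
  }
  sds <- apply(y_clean, 1, sd)
  if (any(sds == 0))
    stop(paste0("region(s) ", paste(which(sds == 0), collapse = ", "),
                " have a constant clean signal; sigma is undefined - ",
                "add a driving input reaching those regions"))
  sigma <- sds / snr
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  noise <- matrix(rnorm(length(y_clean)), nrow(y_clean)) * sigma
  list(y_obs = y_clean + noise, sigma = sigma)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Simulate a complete test dataset
#'
#' Generates the deterministic BOLD response of a model under a design and
#' adds SNR-calibrated Gaussian noise, returning everything the estimation
#' and profiling steps need (including the true generating parameters and
#' the per-region noise SDs, the "known measurement error" the weighted
#' least-squares objective assumes).
#'
#' @inheritParams simulate_clean
#' @inheritParams add_noise
#' @return An object of class `dcm_dataset`: `design`, `y_clean`, `y_obs`,
#'   `sigma`, `snr`, `seed`, `true_params`, `noise_free`.
#' @export
simulate_dataset <- function(model, design, snr, seed, params = NULL,
                             kernel = NULL) {
  if (!is.null(params)) model <- unpack_params(model, as.numeric(params))
  y_clean <- simulate_clean(model, design, kernel = kernel)
  if (isTRUE(attr(y_clean, "diverged")))
    stop("the model diverges under this design; cannot generate data")
  noisy <- add_noise(y_clean, snr, seed)
  structure(list(design = design, y_clean = y_clean, y_obs = noisy$y_obs,
                 sigma = as.numeric(noisy$sigma), snr = snr,
                 seed = as.integer(seed), true_params = pack_params(model),
                 noise_free = isTRUE(attr(noisy$sigma, "noise_free"))),
            class = "dcm_dataset")
}

#' @export
print.dcm_dataset <- function(x, ...) {
  cat(sprintf("Simulated BOLD dataset: %d region(s) x %d volume(s), SNR %s, seed %d\n",
              nrow(x$y_obs), ncol(x$y_obs), format(x$snr), x$seed))
  invisible(x)
}

#' Export / import a dataset as plain text
#'
#' The observations go to `<prefix>.tsv` (one row per volume, one column
#' per region); design, noise SDs, SNR, seed and true parameters go to a
#' `<prefix>.json` sidecar.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param prefix path prefix for the two files.
#' @return `write_dataset()`: the prefix, invisibly. `read_dataset()`: the
#'   reconstructed `dcm_dataset` (with `y_clean` as stored).
#' @export
write_dataset <- function(dataset, prefix) {
  y <- t(dataset$y_obs)
  colnames(y) <- rownames(dataset$y_obs)
  write.table(y, paste0(prefix, ".tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  meta <- list(
    design = .design_to_list(dataset$design),
    sigma = dataset$sigma, snr = dataset$snr, seed = dataset$seed,
    noise_free = dataset$noise_free,
    true_params = as.list(setNames(as.numeric(dataset$true_params),
                                   names(dataset$true_params))),
    y_clean = t(dataset$y_clean))
  jsonlite::write_json(meta, paste0(prefix, ".json"), digits = NA,
                       auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(prefix)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(prefix) {
  y <- as.matrix(read.table(paste0(prefix, ".tsv"), header = TRUE, sep = "\t"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  design <- .design_from_list(meta$design)
  tp <- unlist(meta$true_params)
  structure(list(design = design, y_clean = t(meta$y_clean), y_obs = t(y),
                 sigma = as.numeric(meta$sigma), snr = meta$snr,
                 seed = as.integer(meta$seed), true_params = tp,
                 noise_free = isTRUE(meta$noise_free)),
            class = "dcm_dataset")
}
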