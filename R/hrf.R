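#' Gamma probability density
#'
#' Density of the gamma distribution with shape `h` and rate `l`,
#' \deqn{\Gamma_{pdf}(h, l, t) = l^h t^{h-1} e^{-l t} / \Gamma(h),}
#' the building block of the canonical hemodynamic response function.
#' `l` is treated as a rate: larger `l` compresses the density toward 0.
#'
#' @param h shape parameter (> 0); controls the location of the maximum,
#'   which sits at `(h - 1) / l` for `h > 1`.
#' @param l rate parameter (> 0).
#' @param t time(s) in seconds; the density is 0 for `t < 0`.
#' @return Density values (1/s), vectorized over `t`.
#' @export
gamma_pdf <- function(h, l, t) {
  if (!is.numeric(h) || length(h) != 1 || h <= 0) stop("shape h must be > 0")
  if (!is.numeric(l) || length(l) != 1 || l <= 0) stop("rate l must be > 0")
  out <- numeric(length(t))
  ok <- t >= 0
  out[ok] <- dgamma(t[ok], shape = h, rate = l)
  out
}

#' Canonical double-gamma hemodynamic response function
#'
#' The canonical HRF is the difference of two gamma densities,
#' \deqn{HRF(t) = \Gamma_{pdf}(6, 1, t) - \tfrac{1}{6}\Gamma_{pdf}(16, 1, t),}
#' i.e. a response peaking near 5-6 s followed by an undershoot around
#' 16 s with peak-to-undershoot ratio 6:1.  The kernel is sampled on the
#' microtime grid so that neuronal activity can be convolved with it
#' directly.
#'
#' @param step sampling interval in seconds (0 < step <= 1); use the
#'   design's microtime step.
#' @param support truncation length in seconds (>= 24; default 32).  A
#'   support too short to contain the undershoot triggers a warning.
#' @param peak_delay,undershoot_delay,ratio shape parameters of the two
#'   gamma densities and the peak:undershoot amplitude ratio; defaults are
#'   the canonical 6 s / 16 s / 6.
#' @return An object of class `hrf_kernel`: list with `step`, `support`,
#'   `times` and `values` (first sample at t = 0).
#' @export
canonical_hrf <- function(step, support = 32, peak_delay = 6,
                          undershoot_delay = 16, ratio = 6) {
  if (!is.numeric(step) || step <= 0 || step > 1)
    stop("step must lie in (0, 1] s")
  if (support < 24)
    warning("support shorter than 24 s truncates the undershoot")
  times <- seq(0, support - step / 2, by = step)
  values <- gamma_pdf(peak_delay, 1, times) -
    gamma_pdf(undershoot_delay, 1, times) / ratio
  structure(list(step = step, support = support, times = times,
                 values = values), class = "hrf_kernel")
}

#' @export
print.hrf_kernel <- function(x, ...) {
  cat(sprintf("HRF kernel: step %g s, support %g s, %d samples, peak %.3g at %.2f s\n",
              x$step, x$support, length(x$values), max(x$values),
              x$times[which.max(x$values)]))
  invisible(x)
}

#' Export an HRF kernel as two-column text
#' @param kernel an [canonical_hrf()] kernel.
#' @param path output file; columns are time (s) and kernel value.
#' @return `path`, invisibly.
#' @export
write_hrf <- function(kernel, path) {
  write.table(data.frame(time = kernel$times, value = kernel$values),
              path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}
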