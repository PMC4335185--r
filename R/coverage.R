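#' Empirical coverage of the profile-likelihood confidence intervals
#'
#' Calibration utility: repeatedly simulates data from the model under the
#' same design and noise level, re-estimates the parameters, profiles them
#' and records whether each true parameter value falls inside its
#' likelihood-based CI.  For well-calibrated point-wise 95% intervals the
#' coverage should be close to 0.95.
#'
#' @param model a [dcm_model()] with generating parameter values.
#' @param design a [design_spec()].
#' @param snr signal-to-noise ratio of each replicate.
#' @param n_rep number of replicate simulations.
#' @param base_seed seed root; replicate `r` uses `base_seed + r`.
#' @param settings a [profile_settings()] list.
#' @param start_magnitude start perturbation per replicate (default 0.1).
#' @return A list with `coverage` (overall fraction covered), `per_param`
#'   (per-parameter fractions), `n_used` (replicates with a converged
#'   fit), `n_rep`.
#' @export
ci_coverage <- function(model, design, snr, n_rep = 100, base_seed = 1L,
                        settings = profile_settings(),
                        start_magnitude = 0.1) {
  truth <- as.numeric(pack_params(model))
  np <- length(truth)
  hits <- matrix(NA, n_rep, np)
  for (r in seq_len(n_rep)) {
    rep_out <- tryCatch(
      assess_model(model, design, snr, seed = base_seed + r,
                   settings = settings, start_magnitude = start_magnitude),
      error = function(e) NULL)
    if (is.null(rep_out) || !isTRUE(rep_out$fit$converged)) next
    hits[r, ] <- rep_out$cis$lower <= truth & truth <= rep_out$cis$upper
  }
  used <- stats::complete.cases(hits)
  list(coverage = mean(hits[used, ], na.rm = TRUE),
       per_param = colMeans(hits[used, , drop = FALSE]),
       n_used = sum(used), n_rep = n_rep)
}
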