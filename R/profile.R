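#' Chi-square threshold for likelihood-based confidence intervals
#'
#' The likelihood-based CI of a parameter is the set
#' `{theta : chi2(theta) - chi2(theta_hat) < delta}` with `delta` the
#' `(1 - alpha)` quantile of the chi-square distribution.  Point-wise CIs
#' use `df = 1`; `alpha = 0.05` gives the conventional 95% threshold
#' 3.841.
#'
#' @param alpha significance level in (0, 1).
#' @param df degrees of freedom (>= 1); 1 for point-wise intervals.
#' @return The threshold `delta_alpha`.
#' @export
chi2_threshold <- function(alpha = 0.05, df = 1) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (df < 1) stop("df must be >= 1")
  qchisq(1 - alpha, df = df)
}

#' Settings for profile-likelihood scans
#'
#' @param alpha,df significance level and degrees of freedom of the
#'   threshold (defaults 0.05 and 1, point-wise 95% CIs).
#' @param max_points maximum scan points per direction (default 100).
#' @param step_min_abs,step_frac initial step
#'   `max(step_min_abs, step_frac * |theta_hat_i|)` (defaults 0.01, 0.05).
#' @param grow,shrink step multipliers: grow when the chi-square increase
#'   per step is below `delta/10`, shrink when above `delta/3`.
#' @param overshoot scan past the threshold by `overshoot * delta` so the
#'   crossing is bracketed for interpolation (default 0.5).
#' @param flat_tol structural-flatness tolerance: total chi-square
#'   variation below `flat_tol * delta` over the whole scanned range, with
#'   neither crossing, classifies the parameter as structurally
#'   non-identifiable (default 0.01).
#' @param control [fit_control()] for the inner re-optimizations; the
#'   default uses a reduced iteration budget since scans are warm-started.
#' @return List of class `dcm_profile_settings`.
#' @export
profile_settings <- function(alpha = 0.05, df = 1, max_points = 100,
                             step_min_abs = 0.01, step_frac = 0.05,
                             grow = 1.5, shrink = 0.5, overshoot = 0.5,
                             flat_tol = 0.01,
                             control = fit_control(maxiter = 100, restarts = 0)) {
  structure(list(alpha = alpha, df = df, max_points = max_points,
                 step_min_abs = step_min_abs, step_frac = step_frac,
                 grow = grow, shrink = shrink, overshoot = overshoot,
                 flat_tol = flat_tol, control = control),
            class = "dcm_profile_settings")
}

#' Profile likelihood of one parameter
#'
#' Scans parameter `i` outward from its estimate in both directions with
#' adaptive steps, re-optimizing all other parameters at every grid point
#' (warm-started from the neighbouring point's optimum):
#' `chi2_PL(theta_i) = min over theta_{j != i} of chi2(theta)`.  Each
#' direction stops once the profile exceeds the threshold by the
#' overshoot margin, the point budget is exhausted, or the divergence cap
#' is hit.
#'
#' @param i parameter position in packing order.
#' @param fit a converged [fit_dcm()] result.
#' @param model,data the model and dataset of the fit.
#' @param settings a [profile_settings()] list.
#' @param fixed_idx,fixed_values positions held fixed during the global
#'   fit; they stay fixed at these values during the re-optimizations.
#' @return An object of class `dcm_profile`: `param_index`, `label`,
#'   `theta_grid`, `chi2_pl`, `chi2_hat`, `capped`.
#' @export
profile_parameter <- function(i, fit, model, data,
                              settings = profile_settings(),
                              fixed_idx = integer(0),
                              fixed_values = numeric(0)) {
  if (!isTRUE(fit$converged)) stop("profiling requires a converged fit")
  map <- param_map(model)
  np <- nrow(map)
  if (i < 1 || i > np) stop("parameter index out of range")
  delta <- chi2_threshold(settings$alpha, settings$df)
  theta_hat <- as.numeric(fit$theta_hat)
  chi2_hat <- fit$chi2_min

  scan_dir <- function(dir) {
    d0 <- max(settings$step_min_abs, settings$step_frac * abs(theta_hat[i]))
    d <- d0
    th_prev <- theta_hat[i]
    warm <- theta_hat
    prev_chi2 <- chi2_hat
    grid <- numeric(0); chi2s <- numeric(0); caps <- logical(0)
    for (k in seq_len(settings$max_points)) {
      inner <- NULL; th_i <- th_prev
      for (retry in 1:10) {  # retract oversized steps so the crossing is
        th_i <- th_prev + dir * d  # bracketed by a fine enough pair
        inner <- tryCatch(
          fit_dcm(model, data, start = warm, fixed_idx = c(i, fixed_idx),
                  fixed_values = c(th_i, fixed_values),
                  control = settings$control),
          error = function(e) NULL)
        bad <- is.null(inner) || .fit_capped(inner)
        if (bad || d <= d0 * 2^-9) break
        if (inner$chi2_min - prev_chi2 > delta / 3 &&
            prev_chi2 - chi2_hat < delta * (1 + settings$overshoot)) {
          d <- d * settings$shrink
        } else break
      }
      if (is.null(inner) || .fit_capped(inner)) {
        grid <- c(grid, th_i); chi2s <- c(chi2s, .CHI2_CAP)
        caps <- c(caps, TRUE)
        break  # divergence cap hit: stop this direction
      }
      grid <- c(grid, th_i); chi2s <- c(chi2s, inner$chi2_min)
      caps <- c(caps, FALSE)
      th_prev <- th_i
      warm <- if (inner$diverged_during_fit) theta_hat else
        as.numeric(inner$theta_hat)
      rise <- inner$chi2_min - chi2_hat
      if (rise > delta * (1 + settings$overshoot)) break
      if (inner$chi2_min - prev_chi2 < delta / 10) d <- d * settings$grow
      prev_chi2 <- inner$chi2_min
    }
    list(grid = grid, chi2 = chi2s, caps = caps)
  }

  left <- scan_dir(-1); right <- scan_dir(+1)
  theta_grid <- c(rev(left$grid), theta_hat[i], right$grid)
  chi2_pl <- c(rev(left$chi2), chi2_hat, right$chi2)
  capped <- c(rev(left$caps), FALSE, right$caps)
  structure(list(param_index = i, label = map$label[i],
                 theta_grid = theta_grid, chi2_pl = chi2_pl,
                 chi2_hat = chi2_hat, capped = capped,
                 theta_hat_i = theta_hat[i], delta = delta),
            class = "dcm_profile")
}

# an inner re-optimization whose best point still sits in the diverging
# regime (objective pinned at the cap without convergence)
.fit_capped <- function(fit) {
  !is.finite(fit$chi2_min) || (fit$chi2_min >= .CHI2_CAP && !fit$converged)
}

#' Likelihood-based confidence interval from a profile curve
#'
#' Bounds are located by linear interpolation between the grid points
#' bracketing the crossing of `chi2_hat + delta` on each side of the
#' estimate.  A missing crossing gives an infinite bound on that side and
#' a practical non-identifiability; a curve whose total variation stays
#' below the flatness tolerance with neither crossing is structurally
#' non-identifiable (exact parameter compensation).
#'
#' @param curve a [profile_parameter()] result.
#' @param delta threshold; defaults to the one stored in the curve.
#' @param flat_tol flatness tolerance as a fraction of `delta`
#'   (default 0.01).
#' @return An object of class `dcm_ci`: `lower`, `upper`, `alpha`
#'   (if known), `status`, `contains_zero`.
#' @export
extract_ci <- function(curve, delta = NULL, flat_tol = 0.01) {
  if (length(curve$theta_grid) == 0) stop("empty profile curve")
  if (is.null(delta)) delta <- curve$delta
  thr <- curve$chi2_hat + delta
  ord <- order(curve$theta_grid)
  th <- curve$theta_grid[ord]; ch <- curve$chi2_pl[ord]
  ci <- which.min(abs(th - curve$theta_hat_i))

  cross_out <- function(idx_seq) {
    # walk outward from the estimate; return interpolated crossing or NA
    prev <- ci
    for (j in idx_seq) {
      if (ch[j] >= thr && ch[prev] < thr) {
        return(th[prev] + (thr - ch[prev]) * (th[j] - th[prev]) /
                 (ch[j] - ch[prev]))
      }
      if (ch[j] >= thr) return(th[j])
      prev <- j
    }
    NA_real_
  }
  lower <- if (ci > 1) cross_out(seq(ci - 1, 1)) else NA_real_
  upper <- if (ci < length(th)) cross_out(seq(ci + 1, length(th))) else NA_real_

  finite_ch <- ch[is.finite(ch) & ch < .CHI2_CAP]
  flat <- length(finite_ch) > 1 &&
    (max(finite_ch) - min(finite_ch)) < flat_tol * delta
  status <- if (!is.na(lower) && !is.na(upper)) "identifiable"
  else if (is.na(lower) && is.na(upper)) {
    if (flat) "structurally-non-identifiable"
    else "practically-non-identifiable-both"
  } else if (is.na(lower)) {
    if (flat) "structurally-non-identifiable"
    else "practically-non-identifiable-lower"
  } else {
    if (flat) "structurally-non-identifiable"
    else "practically-non-identifiable-upper"
  }
  lo <- if (is.na(lower)) -Inf else lower
  up <- if (is.na(upper)) Inf else upper
  structure(list(lower = lo, upper = up, status = status,
                 contains_zero = lo <= 0 && 0 <= up),
            class = "dcm_ci")
}

#' @export
print.dcm_ci <- function(x, ...) {
  cat(sprintf("[%s, %s]  %s%s\n", format(x$lower), format(x$upper), x$status,
              if (x$contains_zero) "  (contains zero)" else ""))
  invisible(x)
}

#' Mean confidence-interval width (A-optimality criterion)
#'
#' The design-level criterion is the mean CI width across all parameters.
#' Non-identifiable parameters have infinite CIs, so any infinite bound
#' makes the criterion infinite.
#'
#' @param cis list of [extract_ci()] results, or a `dcm_report`.
#' @return The mean width, or `Inf`.
#' @export
mean_ci <- function(cis) {
  if (inherits(cis, "dcm_report")) cis <- cis$cis_list
  if (length(cis) == 0) stop("at least one parameter is required")
  widths <- vapply(cis, function(ci) ci$upper - ci$lower, 0)
  mean(widths)
}

#' Full identifiability assessment of a model under a design
#'
#' End-to-end driver: simulate a dataset at the given SNR, estimate all
#' parameters from a perturbed start (each free parameter shifted by
#' +/- 0.1), profile every parameter, extract its confidence interval and
#' identifiability status, and compute the design-level mean-CI
#' criterion.  Fully reproducible given the seed.
#'
#' @param model a [dcm_model()] carrying the generating parameter values.
#' @param design a [design_spec()].
#' @param snr signal-to-noise ratio of the simulated data.
#' @param seed integer seed driving noise and start perturbation.
#' @param params optional generating parameters (packing order).
#' @param settings a [profile_settings()] list.
#' @param start_magnitude perturbation of the start values (default 0.1).
#' @param fit_ctl [fit_control()] for the global fit.
#' @return An object of class `dcm_report`: `fit`, `profiles`, `cis`
#'   (data frame), `cis_list`, `mci`, `design`, `snr`, `seed`.
#' @export
assess_model <- function(model, design, snr, seed, params = NULL,
                         settings = profile_settings(),
                         start_magnitude = 0.1, fit_ctl = fit_control()) {
  if (!is.null(params)) model <- unpack_params(model, as.numeric(params))
  data <- simulate_dataset(model, design, snr, seed)
  start <- perturb_start(data$true_params, start_magnitude, seed + 1L)
  fit <- fit_dcm(model, data, start = start, control = fit_ctl)
  map <- param_map(model)
  np <- nrow(map)

  if (!isTRUE(fit$converged)) {
    cis <- data.frame(parameter = map$label,
                      truth = as.numeric(data$true_params),
                      estimate = NA_real_, lower = NA_real_,
                      upper = NA_real_, status = "undetermined",
                      contains_zero = NA, stringsAsFactors = FALSE)
    return(structure(list(fit = fit, profiles = list(), cis = cis,
                          cis_list = list(), mci = NA_real_,
                          design = design, snr = snr, seed = seed,
                          data = data,
                          diagnostic = "fit did not converge after restarts"),
                     class = "dcm_report"))
  }

  profiles <- vector("list", np)
  cis_list <- vector("list", np)
  for (i in seq_len(np)) {
    profiles[[i]] <- profile_parameter(i, fit, model, data, settings)
    cis_list[[i]] <- extract_ci(profiles[[i]], flat_tol = settings$flat_tol)
  }
  cis <- data.frame(
    parameter = map$label,
    truth = as.numeric(data$true_params),
    estimate = as.numeric(fit$theta_hat),
    lower = vapply(cis_list, `[[`, 0, "lower"),
    upper = vapply(cis_list, `[[`, 0, "upper"),
    status = vapply(cis_list, `[[`, "", "status"),
    contains_zero = vapply(cis_list, `[[`, TRUE, "contains_zero"),
    stringsAsFactors = FALSE)
  structure(list(fit = fit, profiles = profiles, cis = cis,
                 cis_list = cis_list, mci = mean_ci(cis_list),
                 design = design, snr = snr, seed = seed, data = data),
            class = "dcm_report")
}

#' @export
print.dcm_report <- function(x, ...) {
  cat(sprintf("Identifiability report (SNR %s, seed %d)\n",
              format(x$snr), x$seed))
  if (!is.null(x$diagnostic)) cat("  diagnostic:", x$diagnostic, "\n")
  print(x$cis, row.names = FALSE)
  cat(sprintf("mCI = %s\n", if (is.finite(x$mci)) format(round(x$mci, 4))
              else "inf"))
  invisible(x)
}
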