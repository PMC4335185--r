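#' Weighted least-squares objective
#'
#' The agreement of a candidate parameter vector with the data is measured
#' by the weighted sum of squared residuals
#' \deqn{\chi^2(\theta) = \sum_i \sum_k (Y_i(t_k) - \hat Y_i(t_k, \theta))^2 / \sigma_i^2,}
#' with the model prediction from [simulate_clean()] and the per-region
#' noise SDs as weights.  For Gaussian noise this equals
#' `-2 log L(theta) + const`, so its minimizer is the maximum-likelihood
#' estimate.  If the candidate trajectory diverges, the divergence cap
#' (1e12) is returned instead of a partial sum.
#'
#' For noise-free datasets (`snr = Inf`) a tiny working SD
#' (`sd(y_clean) * 1e-4` per region) stands in for the zero noise level.
#'
#' @param params numeric parameter vector in packing order.
#' @param model a [dcm_model()].
#' @param data a [simulate_dataset()] result (or compatible list).
#' @return The objective value.
#' @export
chi_squared <- function(params, model, data) {
  if (any(!is.finite(params))) stop("parameters must be finite")
  ctx <- .sim_context(model, data$design)
  sum(.residuals_ctx(as.numeric(params), model, data, ctx)^2)
}

.sigma_working <- function(data) {
  if (isTRUE(data$noise_free) || all(data$sigma == 0))
    apply(data$y_clean, 1, sd) * 1e-4  # noise-free limit: tiny working SD
  else data$sigma
}

.residuals_ctx <- function(theta, model, data, ctx, sigma = NULL) {
  if (is.null(sigma)) sigma <- .sigma_working(data)
  model <- unpack_params(model, theta)
  sim <- .sim_bold_ctx(ctx, model$a_values, .b_cube(model), model$c_values)
  n <- length(data$y_obs)
  if (sim$diverged) {
    r <- rep(sqrt(.CHI2_CAP / n), n)
    attr(r, "diverged") <- TRUE
    return(r)
  }
  as.numeric((data$y_obs - sim$y) / sigma)
}

#' Optimizer settings for the Levenberg-Marquardt fit
#'
#' @param maxiter maximum LM iterations (default 500).
#' @param gtol gradient (orthogonality) tolerance, 1e-8.
#' @param xtol relative step tolerance, 1e-10.
#' @param ftol relative reduction tolerance, 1e-10.
#' @param epsfcn forward-difference scale for the numeric Jacobian;
#'   1e-12 gives difference steps of about 1e-6.
#' @param restarts divergence-restart budget (default 5).
#' @return List of class `dcm_fit_control`.
#' @export
fit_control <- function(maxiter = 500, gtol = 1e-8, xtol = 1e-10,
                        ftol = 1e-10, epsfcn = 1e-12, restarts = 5) {
  structure(list(maxiter = maxiter, gtol = gtol, xtol = xtol, ftol = ftol,
                 epsfcn = epsfcn, restarts = restarts),
            class = "dcm_fit_control")
}

#' Maximum-likelihood estimation of all free DCM parameters
#'
#' Minimizes the weighted residual vector `(Y - Yhat) / sigma` with the
#' Levenberg-Marquardt algorithm ([minpack.lm::nls.lm]).  If the optimizer
#' lands in a diverging parameter regime, the fit is restarted from start
#' values with modified off-diagonal `A` entries (sign flips and damping;
#' inhibitory self-connections are preserved), up to the restart budget.
#' An exhausted budget yields `converged = FALSE`, never an error.
#'
#' @param model a [dcm_model()].
#' @param data a [simulate_dataset()] result.
#' @param start start parameter vector (packing order); defaults to the
#'   dataset's true generating parameters, the simulation analogue of
#'   starting from a previous model inversion (perturb with
#'   [perturb_start()] for a realistic start).
#' @param fixed_idx,fixed_values positions (in packing order) held fixed
#'   at the given values during optimization; used by the profiling step.
#' @param control a [fit_control()] list.
#' @return An object of class `dcm_fit`: `theta_hat` (full named vector,
#'   fixed entries included), `chi2_min`, `converged`,
#'   `diverged_during_fit`, `n_restarts`, `info`, `message`.
#' @export
fit_dcm <- function(model, data, start = NULL, fixed_idx = integer(0),
                    fixed_values = numeric(0), control = fit_control()) {
  map <- param_map(model)
  np <- nrow(map)
  if (is.null(start)) start <- data$true_params
  start <- as.numeric(start)
  if (length(start) != np) stop("start vector does not match the model masks")
  if (length(fixed_idx) != length(fixed_values))
    stop("fixed_idx and fixed_values must have the same length")
  ctx <- .sim_context(model, data$design)
  free_idx <- setdiff(seq_len(np), fixed_idx)
  sigma <- .sigma_working(data)

  assemble <- function(theta_free) {
    th <- numeric(np)
    th[fixed_idx] <- fixed_values
    th[free_idx] <- theta_free
    th
  }
  resfun <- function(theta_free)
    .residuals_ctx(assemble(theta_free), model, data, ctx, sigma)

  lmctl <- minpack.lm::nls.lm.control(
    maxiter = control$maxiter, gtol = control$gtol, ptol = control$xtol,
    ftol = control$ftol, epsfcn = control$epsfcn,
    maxfev = 100 * control$maxiter)

  a_off <- which(map$matrix == "A" & map$row != map$col)
  best <- NULL; used_restarts <- 0L; diverged_any <- FALSE
  for (r in 0:control$restarts) {
    try_start <- start
    if (r > 0) {
      # "changing the sign of a few parameters": damp, flip, then zero the
      # off-diagonal A entries of the start vector, keeping the inhibitory
      # self-connections, until a non-diverging start is found.
      if (length(a_off)) {
        fac <- switch(((r - 1) %% 4) + 1, 0.5, -1, -0.5, 0)
        try_start[a_off] <- start[a_off] * fac
      }
      used_restarts <- r
    }
    if (length(free_idx) == 0L) {
      chi2 <- sum(resfun(numeric(0))^2)
      best <- list(par = numeric(0), deviance = chi2, info = 1L,
                   message = "no free parameters")
      break
    }
    # a start on the divergence plateau has a vanishing gradient, and one
    # with an objective beyond the cap is indistinguishable from it; skip
    r0 <- resfun(try_start[free_idx])
    if (isTRUE(attr(r0, "diverged")) || sum(r0^2) >= .CHI2_CAP) {
      diverged_any <- TRUE
      next
    }
    res <- tryCatch(
      suppressWarnings(  # nls.lm warns on hitting maxiter; the info code
        minpack.lm::nls.lm(par = try_start[free_idx], fn = resfun,
                           control = lmctl)),  # is handled below instead
      error = function(e) NULL)
    if (is.null(res)) { diverged_any <- TRUE; next }
    chi2 <- res$deviance
    if (isTRUE(attr(resfun(res$par), "diverged"))) {
      diverged_any <- TRUE
      next  # the optimum itself sits in a diverging regime
    }
    if (is.null(best) || chi2 < best$deviance) best <- res
    if (res$info %in% 1:3) break  # converged; otherwise keep trying restarts
  }

  if (is.null(best)) {
    return(structure(list(
      theta_hat = setNames(start, map$label), chi2_min = .CHI2_CAP,
      converged = FALSE, diverged_during_fit = TRUE,
      n_restarts = used_restarts, info = NA_integer_,
      message = "restart budget exhausted in a diverging regime"),
      class = "dcm_fit"))
  }
  theta_hat <- assemble(if (length(free_idx)) best$par else numeric(0))
  structure(list(
    theta_hat = setNames(theta_hat, map$label), chi2_min = best$deviance,
    converged = is.finite(best$deviance) && best$info %in% 1:4,
    diverged_during_fit = diverged_any, n_restarts = used_restarts,
    info = best$info, message = best$message), class = "dcm_fit")
}

#' @export
print.dcm_fit <- function(x, ...) {
  cat(sprintf("DCM fit: chi2 = %.6g, converged = %s (restarts %d)\n",
              x$chi2_min, x$converged, x$n_restarts))
  print(round(x$theta_hat, 4))
  invisible(x)
}

#' Perturb a parameter vector into start values
#'
#' Shifts every free parameter by `+magnitude` or `-magnitude` with
#' independent random signs, emulating start values taken as a slightly
#' changed previous estimate.
#'
#' @param params numeric parameter vector.
#' @param magnitude absolute shift (>= 0), default 0.1.
#' @param seed integer seed; the same seed reproduces the same signs.
#' @return The perturbed vector (names preserved).
#' @export
perturb_start <- function(params, magnitude = 0.1, seed = 1L) {
  if (magnitude < 0) stop("magnitude must be >= 0")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  signs <- sample(c(-1, 1), length(params), replace = TRUE)
  params + magnitude * signs
}
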