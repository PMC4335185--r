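test_that("the chi-square threshold is the (1 - alpha) quantile", {
  expect_equal(chi2_threshold(0.05, 1), 3.841, tolerance = 1e-3)
  expect_equal(chi2_threshold(0.32, 1), qchisq(0.68, 1), tolerance = 1e-9)
  expect_equal(round(chi2_threshold(0.32, 1), 2), 0.99)
  expect_gt(chi2_threshold(0.05, 2), chi2_threshold(0.05, 1))
  expect_error(chi2_threshold(0), "alpha")
  expect_error(chi2_threshold(1.2), "alpha")
})

test_that("CI extraction classifies parabolic, one-sided and flat curves", {
  mk_curve <- function(grid, chi2, hat_i, chi2_hat = 0) {
    structure(list(param_index = 1L, label = "toy", theta_grid = grid,
                   chi2_pl = chi2, chi2_hat = chi2_hat,
                   capped = rep(FALSE, length(grid)), theta_hat_i = hat_i,
                   delta = 1), class = "dcm_profile")
  }
  # parabola (theta - 2)^2 scanned over [0, 4] with delta = 1 -> CI [1, 3]
  g <- seq(0, 4, by = 0.1)
  ci <- extract_ci(mk_curve(g, (g - 2)^2, 2), delta = 1)
  expect_equal(ci$lower, 1, tolerance = 1e-9)
  expect_equal(ci$upper, 3, tolerance = 1e-9)
  expect_equal(ci$status, "identifiable")
  expect_false(ci$contains_zero)
  # decreasing-then-flat on the right: upper bound missing
  g2 <- seq(0, 6, by = 0.1)
  chi2 <- ifelse(g2 < 2, (g2 - 2)^2, 0)
  ci2 <- extract_ci(mk_curve(g2, chi2, 2), delta = 1)
  expect_equal(ci2$lower, 1, tolerance = 1e-9)
  expect_equal(ci2$upper, Inf)
  expect_equal(ci2$status, "practically-non-identifiable-upper")
  # constant curve: structural
  ci3 <- extract_ci(mk_curve(g2, rep(0.001, length(g2)), 2), delta = 1)
  expect_equal(ci3$status, "structurally-non-identifiable")
  expect_equal(ci3$lower, -Inf)
  expect_true(ci3$contains_zero)
})

test_that("the mean-CI criterion averages widths and is infinite with any open bound", {
  ci <- function(lo, up) structure(list(lower = lo, upper = up,
                                        status = "x", contains_zero = FALSE),
                                   class = "dcm_ci")
  expect_equal(mean_ci(list(ci(0, 0.2), ci(1, 1.4))), 0.3)
  expect_equal(mean_ci(list(ci(0, 0.2), ci(-Inf, 1))), Inf)
  expect_equal(mean_ci(list(ci(0.1, 0.6))), 0.5)
  expect_error(mean_ci(list()), "parameter")
})

test_that("profile CI of a linear model matches the analytic 1.96-sigma interval", {
  # single free driving strength with a11 fixed: y = theta * g, so the
  # profile is an exact parabola with CI theta_hat +/- sqrt(delta)*sigma_theta
  m <- one_region_model(a = -0.5, c = 0.8)
  d <- block_design(tr = 2, n_slices = 2, n_volumes = 90)
  ds <- simulate_dataset(m, d, 5, 21)
  g <- as.numeric(simulate_clean(m, d, params = c(-0.5, 1)))
  ft <- fit_dcm(m, ds, start = c(-0.5, 0.5), fixed_idx = 1, fixed_values = -0.5)
  curve <- profile_parameter(2, ft, m, ds, test_settings(),
                             fixed_idx = 1, fixed_values = -0.5)
  ci <- extract_ci(curve)
  se <- ds$sigma / sqrt(sum(g^2))
  expect_equal(ci$status, "identifiable")
  expect_equal(ci$upper - ci$lower, 2 * sqrt(chi2_threshold(0.05, 1)) * se,
               tolerance = 0.02)
  expect_equal((ci$upper + ci$lower) / 2, as.numeric(ft$theta_hat[2]),
               tolerance = 1e-3)
})

test_that("exact parameter compensation yields a flat, structural profile", {
  # two driving inputs with identical stimulus trains: only c1 + c2 is
  # determined; the profile of c1 must be flat
  st <- data.frame(onset = c(0, 40, 80, 120), duration = 20)
  m <- two_input_model(a = -0.5, c1 = 0.5, c2 = 0.3)
  d <- design_spec(2, 2, 80, stimuli = list(in1 = st, in2 = st))
  ds <- simulate_dataset(m, d, 10, 31)
  ft <- fit_dcm(m, ds, start = as.numeric(ds$true_params))
  st2 <- test_settings(max_points = 12)
  curve <- profile_parameter(2, ft, m, ds, st2)
  ci <- extract_ci(curve, flat_tol = st2$flat_tol)
  expect_equal(ci$status, "structurally-non-identifiable")
  expect_equal(ci$lower, -Inf)
  expect_equal(ci$upper, Inf)
  # and the sum stays put while c1 roams
  expect_lt(max(curve$chi2_pl) - min(curve$chi2_pl), 0.01 * curve$delta)
})

test_that("the profile minimum sits at the estimate and contains it in the CI", {
  mc <- chain_model()
  dd <- block_design(n_volumes = 60)
  ds <- simulate_dataset(mc, dd, 10, 41)
  ft <- fit_dcm(mc, ds, start = perturb_start(ds$true_params, 0.1, 42))
  expect_true(ft$converged)
  for (i in c(1L, 4L)) {
    curve <- profile_parameter(i, ft, mc, ds, test_settings())
    expect_true(ft$theta_hat[i] %in% curve$theta_grid)
    expect_gte(min(curve$chi2_pl), curve$chi2_hat - 1e-6)
    ci <- extract_ci(curve)
    expect_equal(ci$status, "identifiable")
    expect_lte(ci$lower, ft$theta_hat[i])
    expect_gte(ci$upper, ft$theta_hat[i])
  }
})

test_that("profile CIs agree with a brute-force two-parameter grid", {
  # one region, free (a11, c11); dense 2-D chi2 evaluation followed by
  # exact per-column minimization is the independent oracle
  m <- one_region_model(a = -0.5, c = 0.8)
  d <- block_design(tr = 2, n_slices = 2, n_volumes = 90)
  ds <- simulate_dataset(m, d, 5, 51)
  ft <- fit_dcm(m, ds, start = c(-0.45, 0.75))
  curve <- profile_parameter(2, ft, m, ds, test_settings())
  ci <- extract_ci(curve)

  width <- ci$upper - ci$lower
  ctx <- dcmprofile:::.sim_context(m, d)
  obj <- function(th) sum(dcmprofile:::.residuals_ctx(th, m, ds, ctx)^2)
  a_grid <- seq(-0.75, -0.30, length.out = 151)
  c_grid <- seq(ci$lower - 0.6 * width, ci$upper + 0.6 * width,
                length.out = 161)
  pl <- vapply(c_grid, function(cc)
    min(vapply(a_grid, function(aa) obj(c(aa, cc)), 0)), 0)
  thr <- min(pl) + chi2_threshold(0.05, 1)
  crossing <- function(idx_from, idx_to) {
    ii <- idx_from:idx_to
    k <- which(diff(pl[ii] < thr) != 0)[1]
    j <- ii[k]; jn <- ii[k + 1]
    c_grid[j] + (thr - pl[j]) * (c_grid[jn] - c_grid[j]) / (pl[jn] - pl[j])
  }
  i_min <- which.min(pl)
  lower_bf <- crossing(1, i_min)
  upper_bf <- crossing(i_min, length(c_grid))
  expect_lt(abs(ci$lower - lower_bf), 0.02 * width)
  expect_lt(abs(ci$upper - upper_bf), 0.02 * width)
})

test_that("noise-free data yield far narrower CIs than SNR 10", {
  mc <- chain_model()
  dd <- block_design(n_volumes = 60)
  st <- test_settings(max_points = 20)
  rep10 <- assess_model(mc, dd, snr = 10, seed = 61, settings = st)
  rep_nf <- assess_model(mc, dd, snr = Inf, seed = 61, settings = st)
  w10 <- rep10$cis$upper - rep10$cis$lower
  wnf <- rep_nf$cis$upper - rep_nf$cis$lower
  expect_true(all(is.finite(w10)) && all(is.finite(wnf)))
  expect_true(all(wnf < w10))
})
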