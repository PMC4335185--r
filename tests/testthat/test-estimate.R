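test_that("chi-squared matches hand arithmetic and the likelihood identity", {
  m <- one_region_model()
  d <- design_spec(10, 10, 2, stimuli = list(drive = data.frame(onset = 0, duration = 10)))
  y_clean <- simulate_clean(m, d)
  # residuals (1, 2) with sigma = 1 give 1^2 + 2^2 = 5
  ds <- structure(list(design = d, y_clean = y_clean,
                       y_obs = y_clean + matrix(c(1, 2), 1),
                       sigma = 1, snr = NA, seed = 0L,
                       true_params = pack_params(m), noise_free = FALSE),
                  class = "dcm_dataset")
  expect_equal(chi_squared(as.numeric(pack_params(m)), m, ds), 5)

  # chi2(theta) = -2 log L(theta) + const across random parameter vectors
  mc <- chain_model()
  dd <- block_design(n_volumes = 30)
  data <- simulate_dataset(mc, dd, 5, 4)
  loglik <- function(theta) {
    yhat <- simulate_clean(mc, dd, params = theta)
    r <- (data$y_obs - yhat) / data$sigma
    sum(-0.5 * r^2 - 0.5 * log(2 * pi * (data$sigma^2)[row(r)]))
  }
  set.seed(9)
  consts <- replicate(5, {
    theta <- as.numeric(data$true_params) + rnorm(4, sd = 0.05)
    chi_squared(theta, mc, data) + 2 * loglik(theta)
  })
  expect_lt(max(consts) - min(consts), 1e-8)
})

test_that("chi-squared returns the divergence cap, not a partial sum", {
  fx <- load_fixture("forward")
  ds <- simulate_dataset(fx$model, vary_session(fx$design, 60), 10, 2)
  bad <- replace(as.numeric(ds$true_params), 1, +0.5)
  expect_equal(chi_squared(bad, fx$model, ds), 1e12)
  expect_error(chi_squared(c(NA, as.numeric(ds$true_params)[-1]), fx$model, ds),
               "finite")
})

test_that("the optimizer recovers the truth from a perfect and a perturbed start", {
  mc <- chain_model()
  dd <- block_design(n_volumes = 60)
  truth <- as.numeric(pack_params(mc))
  # noise-free data, start at truth: stay there
  ds0 <- simulate_dataset(mc, dd, Inf, 1)
  f0 <- fit_dcm(mc, ds0)
  expect_true(f0$converged)
  expect_lt(f0$chi2_min, 1e-8)
  expect_equal(as.numeric(f0$theta_hat), truth, tolerance = 1e-6)
  # noisy data: a converged fit cannot exceed the feasible truth point
  ds <- simulate_dataset(mc, dd, 10, 5)
  start <- perturb_start(ds$true_params, 0.1, 6)
  ft <- fit_dcm(mc, ds, start = start)
  expect_true(ft$converged)
  expect_lte(ft$chi2_min, chi_squared(truth, mc, ds))
})

test_that("a linear-in-parameters model reproduces the closed-form WLS solution", {
  # with a11 fixed, y = theta1 * g1 + theta2 * g2 is linear in the two
  # driving strengths; the normal equations are the independent oracle
  m <- two_input_model(a = -0.5, c1 = 0.7, c2 = -0.3)
  st1 <- data.frame(onset = c(0, 80), duration = 20)
  st2 <- data.frame(onset = c(40, 120), duration = 20)
  d <- design_spec(2, 2, 80, stimuli = list(in1 = st1, in2 = st2))
  ds <- simulate_dataset(m, d, 5, 8)
  g1 <- as.numeric(simulate_clean(m, d, params = c(-0.5, 1, 0)))
  g2 <- as.numeric(simulate_clean(m, d, params = c(-0.5, 0, 1)))
  X <- cbind(g1, g2)
  w_ls <- solve(t(X) %*% X, t(X) %*% as.numeric(ds$y_obs))  # sigma is scalar
  ft <- fit_dcm(m, ds, start = c(-0.5, 0, 0), fixed_idx = 1,
                fixed_values = -0.5)
  expect_equal(as.numeric(ft$theta_hat[2:3]), as.numeric(w_ls),
               tolerance = 1e-6)
})

test_that("start perturbation shifts every parameter by +/- magnitude, reproducibly", {
  theta <- c(a = -0.5, b = 0.3, c = 0.8)
  expect_identical(perturb_start(theta, 0, 1), theta)
  p1 <- perturb_start(theta, 0.1, 3)
  expect_equal(abs(p1 - theta), rep(0.1, 3), ignore_attr = TRUE)
  expect_identical(p1, perturb_start(theta, 0.1, 3))
  expect_false(identical(p1, perturb_start(theta, 0.1, 4)))
})

test_that("the restart heuristic rescues a diverging start", {
  fx <- load_fixture("forward")
  ds <- simulate_dataset(fx$model, vary_session(fx$design, 120), 10, 3)
  start <- perturb_start(ds$true_params, 0.1, 2)
  expect_gte(chi_squared(as.numeric(start), fx$model, ds), 1e12)
  ft <- fit_dcm(fx$model, ds, start = start)
  expect_true(ft$converged)
  expect_true(ft$diverged_during_fit)
  expect_gt(ft$n_restarts, 0)
  expect_lte(ft$chi2_min, chi_squared(as.numeric(ds$true_params), fx$model, ds))
})
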