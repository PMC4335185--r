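test_that("one-region trajectories match the scalar closed forms", {
  # free decay: z(t) = z0 exp(-a t)
  m <- dcm_model(a_mask = matrix(1), a_values = matrix(-0.7),
                 c_mask = matrix(nrow = 1, ncol = 0),
                 c_values = matrix(nrow = 1, ncol = 0))
  d <- design_spec(1, 10, 20)
  tr <- integrate_neuronal(m, d, init = 2)
  expect_false(tr$diverged)
  expect_equal(tr$z[1, ], 2 * exp(-0.7 * tr$times), tolerance = 1e-8)
  expect_equal(tr$z[1, 1], 2)  # initial condition at t = 0

  # constant input: fixed point c/a
  m2 <- one_region_model(a = -0.5, c = 0.8)
  d2 <- design_spec(1, 10, 60,
                    stimuli = list(drive = data.frame(onset = 0, duration = 60)))
  tr2 <- integrate_neuronal(m2, d2)
  expect_equal(tail(tr2$z[1, ], 1), 0.8 / 0.5, tolerance = 1e-6)
})

test_that("piecewise integrator agrees with a fine-step Runge-Kutta oracle", {
  skip_if_not_installed("deSolve")
  fx <- load_fixture("forward")
  d <- vary_session(fx$design, 15)  # 48.3 s window with an input change at 32.2 s
  tr <- integrate_neuronal(fx$model, d)

  # independent oracle: deSolve RK4 at step ts/100, integrated piecewise
  # over the constant-input intervals so no step straddles a stimulus edge
  mdl <- fx$model
  ts <- d$microtime_step
  t_end <- max(tr$times)
  edges <- sort(unique(c(0, 32.2, t_end)))
  z0 <- rep(0, 3)
  zf <- matrix(NA_real_, 3, length(tr$times))
  zf[, 1] <- z0
  for (s in seq_len(length(edges) - 1)) {
    u <- as.numeric(input_values(d, edges[s]))
    M <- mdl$a_values
    for (i in seq_along(u)) if (u[i] != 0) M <- M + mdl$b_values[[i]] * u[i]
    cu <- drop(mdl$c_values %*% u)
    rhs <- function(t, z, p) list(drop(M %*% z + cu))
    fine <- seq(edges[s], edges[s + 1], by = ts / 100)
    sol <- deSolve::ode(y = z0, times = fine, func = rhs, parms = NULL,
                        method = "rk4")
    z0 <- as.numeric(sol[nrow(sol), 2:4])
    in_seg <- which(tr$times > edges[s] & tr$times <= edges[s + 1])
    idx <- match(round(tr$times[in_seg] / (ts / 100)),
                 round(sol[, 1] / (ts / 100)))
    zf[, in_seg] <- t(sol[idx, 2:4])
  }
  expect_lt(max(abs(zf - tr$z)), 1e-6)
})

test_that("within-bin dynamics are linear in the initial state", {
  set.seed(7)
  for (k in 1:5) {
    A <- matrix(rnorm(9, sd = 0.3), 3); diag(A) <- -abs(rnorm(3, 1, 0.2))
    m <- dcm_model(a_mask = matrix(1, 3, 3), a_values = A,
                   c_mask = matrix(0, 3, 1), c_values = matrix(0, 3, 1))
    d <- design_spec(1, 5, 10)  # no inputs: one frozen linear system
    z1 <- rnorm(3); z2 <- rnorm(3); a <- 0.7; b <- -1.3
    t1 <- integrate_neuronal(m, d, init = z1)$z
    t2 <- integrate_neuronal(m, d, init = z2)$z
    t12 <- integrate_neuronal(m, d, init = a * z1 + b * z2)$z
    expect_equal(t12, a * t1 + b * t2, tolerance = 1e-9)
  }
})

test_that("stable systems never flag divergence; unstable ones do", {
  fx <- load_fixture("forward")
  tr <- integrate_neuronal(fx$model, fx$design)
  expect_false(tr$diverged)
  expect_true(all(is.finite(tr$z)))

  unstable <- unpack_params(fx$model, replace(as.numeric(fx$params), 1, +0.5))
  tru <- integrate_neuronal(unstable, fx$design)
  expect_true(tru$diverged)
  y <- observe_bold(tru, canonical_hrf(fx$design$microtime_step), fx$design)
  expect_true(isTRUE(attr(y, "diverged")))
})

test_that("BOLD observation is a causal convolution sampled at the TR grid", {
  d <- design_spec(2, 4, 40)
  ts <- d$microtime_step
  k <- canonical_hrf(ts)
  n_grid <- d$n_slices * d$n_volumes
  # unit impulse of amplitude 1/ts at bin j0 reproduces the kernel shifted
  j0 <- 9L
  z <- matrix(0, 1, n_grid); z[1, j0] <- 1 / ts
  traj <- structure(list(times = (seq_len(n_grid) - 1) * ts, z = z,
                         diverged = FALSE, step = ts), class = "dcm_trajectory")
  y <- observe_bold(traj, k, d)
  vol_bins <- (seq_len(d$n_volumes) - 1) * d$n_slices + 1
  expected <- rep(0, d$n_volumes)
  lag <- vol_bins - j0 + 1  # 1-based kernel index; lag 1 is the t = 0 sample
  ok <- lag >= 1 & lag <= length(k$values)
  expected[ok] <- k$values[lag[ok]]
  expect_equal(as.numeric(y), expected, tolerance = 1e-12)

  # zero activity maps to zero signal, and the map is linear
  z2 <- matrix(rnorm(n_grid), 1)
  trajf <- function(zz) structure(list(times = traj$times, z = zz,
                                       diverged = FALSE, step = ts),
                                  class = "dcm_trajectory")
  expect_equal(as.numeric(observe_bold(trajf(0 * z2), k, d)),
               rep(0, d$n_volumes))
  y1 <- observe_bold(trajf(z2), k, d); y2 <- observe_bold(trajf(z), k, d)
  expect_equal(observe_bold(trajf(2 * z2 - 3 * z), k, d), 2 * y1 - 3 * y2,
               tolerance = 1e-12)
  # kernel/step mismatch is a structural error
  expect_error(observe_bold(traj, canonical_hrf(ts / 2), d), "step")
})

test_that("refining the microtime grid leaves the BOLD response nearly unchanged", {
  fx <- load_fixture("forward")
  d1 <- vary_session(fx$design, 60)
  d2 <- design_spec(d1$tr, d1$n_slices * 2L, d1$n_volumes, d1$stimuli)
  y1 <- simulate_clean(fx$model, d1)
  y2 <- simulate_clean(fx$model, d2)
  expect_lt(max(abs(y2 - y1)) / max(abs(y1)), 1e-3)
})
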