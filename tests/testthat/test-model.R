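test_that("the sigmoid switch has its stated shape", {
  expect_equal(sigmoid_switch(20, k = 0.5, t_switch = 20), 0.5)
  expect_equal(sigmoid_switch(c(-5, 0, 100), k = 0, t_switch = 20),
               rep(0.5, 3))
  expect_equal(sigmoid_switch(30, k = 0.1, t_switch = 20),
               1 / (1 + exp(-1)))

  t <- seq(-50, 150, by = 0.5)
  s <- sigmoid_switch(t, k = 0.3, t_switch = 20)
  expect_true(all(diff(s) >= 0))
  expect_true(all(s >= 0 & s <= 1))
  # saturates cleanly at extreme arguments
  expect_identical(sigmoid_switch(1e6, k = 10, t_switch = 0), 1)
  expect_identical(sigmoid_switch(-1e6, k = 10, t_switch = 0), 0)
  expect_error(sigmoid_switch(0, k = -1),
               class = "phenoswitch_validation_error")
})

test_that("parameter validation enforces the model's domain", {
  expect_error(switching_params(alpha = -1),
               class = "phenoswitch_validation_error")
  expect_error(switching_params(m0 = 1),
               class = "phenoswitch_validation_error")
  expect_error(switching_params(u0 = -0.1),
               class = "phenoswitch_validation_error")
  expect_error(as_switching_params(list(alfa = 1)),
               class = "phenoswitch_validation_error")
  expect_identical(as_switching_params(list(alpha = 2))$alpha, 2)
})

test_that("no source term means no small clusters", {
  params <- switching_params(beta = 0, gamma = 0, u0 = 0)
  traj <- simulate_switching(params, t_end = 48, dt = 0.05)
  expect_true(all(traj$U == 0))
  expect_true(all(traj$fraction_small == 0))
})

test_that("without reversion or noise, small clusters only accumulate", {
  params <- switching_params(alpha = 1, beta = 0.01, gamma = 0,
                             sigma_eta = 0)
  traj <- simulate_switching(params, t_end = 48, dt = 0.05)
  expect_true(all(diff(traj$U) >= 0))
  expect_true(all(traj$M > 1))
  expect_true(all(traj$fraction_small >= 0 & traj$fraction_small <= 1))
})

test_that("Euler growth agrees with an independent high-order integrator", {
  skip_if_not_installed("deSolve")
  params <- switching_params(alpha = 1, beta = 0, gamma = 0, m0 = 2)
  traj <- simulate_switching(params, t_end = 48, dt = 0.01)

  ref <- deSolve::ode(
    y = c(M = 2), times = traj$time_h,
    func = function(t, y, p) list(log2(y[1])),
    parms = NULL, method = "lsoda", rtol = 1e-10, atol = 1e-10
  )
  rel_err <- abs(traj$M - ref[, "M"]) / ref[, "M"]
  expect_lt(max(rel_err), 0.005)
})

test_that("halving the step barely moves the observation-time fractions", {
  params <- switching_params()
  f1 <- predicted_fractions(
    simulate_switching(params, t_end = 48, dt = 0.01), c(12, 20, 24, 48))
  f2 <- predicted_fractions(
    simulate_switching(params, t_end = 48, dt = 0.005), c(12, 20, 24, 48))
  expect_lt(max(abs(f1 - f2)), 1e-4)
})

test_that("deterministic runs are bitwise reproducible, stochastic per seed", {
  params <- switching_params()
  expect_identical(simulate_switching(params, 24, 0.05),
                   simulate_switching(params, 24, 0.05))

  noisy <- switching_params(sigma_eta = 0.05)
  a <- simulate_switching(noisy, 24, 0.05, seed = 9)
  b <- simulate_switching(noisy, 24, 0.05, seed = 9)
  expect_identical(a$M, b$M)
  c <- simulate_switching(noisy, 24, 0.05, seed = 10)
  expect_false(identical(a$M, c$M))
})

test_that("positivity holds across random parameter draws", {
  for (seed in 1:10) {
    params <- withr::with_seed(seed, switching_params(
      alpha = runif(1, 0.2, 2), beta = runif(1, 0, 0.05),
      gamma = runif(1, 0, 0.02), k = runif(1, 0, 1),
      sigma_eta = runif(1, 0, 0.1), m0 = runif(1, 1.5, 4)
    ))
    traj <- simulate_switching(params, t_end = 48, dt = 0.05, seed = seed)
    expect_true(all(traj$M > 1))
    expect_true(all(traj$U >= 0))
    expect_true(all(traj$fraction_small >= 0 & traj$fraction_small <= 1))
  }
})

test_that("unstable steps and invalid grids are refused", {
  expect_error(
    simulate_switching(switching_params(alpha = 50, m0 = 4), 48, dt = 0.1),
    class = "phenoswitch_step_error")
  expect_error(simulate_switching(switching_params(), 48, dt = 0.2),
               class = "phenoswitch_validation_error")
  expect_error(simulate_switching(switching_params(), 48, dt = 0),
               class = "phenoswitch_validation_error")
  expect_error(simulate_switching(switching_params(), 0.001, dt = 0.01),
               class = "phenoswitch_validation_error")
})

test_that("fraction interpolation is linear and range-checked", {
  traj <- simulate_switching(switching_params(), t_end = 24, dt = 0.05)

  # on a grid node: the grid value exactly
  i <- 101
  expect_identical(predicted_fractions(traj, traj$time_h[i]),
                   traj$fraction_small[i])
  # midpoint between nodes: arithmetic mean of the node values
  mid <- (traj$time_h[i] + traj$time_h[i + 1]) / 2
  expect_equal(predicted_fractions(traj, mid),
               (traj$fraction_small[i] + traj$fraction_small[i + 1]) / 2,
               tolerance = 1e-12)

  flat <- tibble::tibble(time_h = 0:10, fraction_small = 0.25)
  expect_equal(predicted_fractions(flat, c(0.5, 7.3)), c(0.25, 0.25))

  expect_error(predicted_fractions(traj, 25),
               class = "phenoswitch_range_error")
  expect_error(predicted_fractions(traj, -1),
               class = "phenoswitch_range_error")
})

test_that("goodness of fit matches hand arithmetic", {
  perfect <- goodness_of_fit(c(0.2, 0.4, 0.6), c(0.2, 0.4, 0.6))
  expect_identical(perfect$r_squared, 1)
  expect_identical(perfect$residual_sd, 0)

  mean_pred <- goodness_of_fit(c(0.2, 0.4, 0.6), rep(0.4, 3))
  expect_identical(mean_pred$r_squared, 0)

  # SS_tot = 0.08, SS_res = 0.0075, R^2 = 1 - 0.09375 = 0.90625
  hand <- goodness_of_fit(c(0.2, 0.4, 0.6), c(0.25, 0.35, 0.65))
  expect_equal(hand$r_squared, 0.90625, tolerance = 1e-12)
  expect_equal(hand$residual_sd, sd(c(-0.05, 0.05, -0.05)),
               tolerance = 1e-12)

  expect_error(goodness_of_fit(rep(0.5, 3), c(0.4, 0.5, 0.6)),
               class = "phenoswitch_degenerate_error")
  expect_error(goodness_of_fit(0.5, 0.5),
               class = "phenoswitch_validation_error")
})
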