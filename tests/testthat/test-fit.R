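test_that("noise-free observations refit to the generating tuple", {
  g <- default_grids()
  truth <- switching_params(alpha = 1, beta = 0.005, gamma = 0, k = 0.1)
  dt <- 0.05
  obs <- generate_timecourse_observations(
    truth, observation_design(binomial_sampling = FALSE, seed = 1),
    dt = dt)
  fit <- fit_switching_grid(obs, g$alpha, g$beta, g$gamma, g$k, dt = dt)

  p <- fit$best_params
  expect_identical(c(p$alpha, p$beta, p$gamma, p$k), c(1, 0.005, 0, 0.1))
  expect_lt(fit$objective_best, 1e-10)

  # identifiability: no other tuple matches to within the tolerance
  others <- fit$grid_table$objective[-which.min(fit$grid_table$objective)]
  expect_true(all(others > 1e-8))

  # the best objective is the minimum of the grid table
  expect_identical(fit$objective_best, min(fit$grid_table$objective))
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("ties in the argmin break toward the smallest tuple", {
  # with beta = 0 the trajectory is independent of k: every k ties at 0
  truth <- switching_params(alpha = 1, beta = 0, gamma = 0)
  dt <- 0.05
  obs <- generate_timecourse_observations(
    truth, observation_design(binomial_sampling = FALSE, seed = 1),
    dt = dt)
  fit <- fit_switching_grid(obs, alpha_grid = 1, beta_grid = 0,
                            gamma_grid = 0, k_grid = c(1, 0.1, 0.5),
                            dt = dt)
  expect_identical(fit$best_params$k, 0.1)
  expect_true(all(fit$grid_table$objective == fit$grid_table$objective[1]))
})

test_that("every tuple on a full grid is recovered by self-fit", {
  g <- default_grids()
  dt <- 0.05
  grid <- tidyr::expand_grid(alpha = g$alpha, beta = g$beta,
                             gamma = g$gamma, k = g$k)
  design <- observation_design(binomial_sampling = FALSE, seed = 1)
  for (i in seq_len(nrow(grid))) {
    truth <- switching_params(alpha = grid$alpha[i], beta = grid$beta[i],
                              gamma = grid$gamma[i], k = grid$k[i])
    obs <- generate_timecourse_observations(truth, design, dt = dt)
    fit <- fit_switching_grid(obs, g$alpha, g$beta, g$gamma, g$k, dt = dt)
    p <- fit$best_params
    recovered <- c(p$alpha, p$beta, p$gamma, p$k)
    expected <- c(grid$alpha[i], grid$beta[i], grid$gamma[i], grid$k[i])
    if (grid$beta[i] == 0) {
      # k is unidentifiable without a source term; tie-break gives min k
      expected[4] <- min(g$k)
      # gamma is unidentifiable when U stays at 0
      expected[3] <- min(g$gamma)
    }
    expect_identical(recovered, expected)
    expect_lt(fit$objective_best, 1e-10)
  }
})

test_that("simulation failures score infinite, never crash the search", {
  obs <- tibble::tibble(time_h = c(12, 48),
                        fraction_small = c(0.01, 0.05))
  fit <- fit_switching_grid(obs, alpha_grid = c(1, 50),
                            beta_grid = 0.005, gamma_grid = 0,
                            k_grid = 0.001, dt = 0.1, m0 = 4)
  bad <- fit$grid_table$objective[fit$grid_table$alpha == 50]
  expect_identical(bad, Inf)
  expect_identical(fit$best_params$alpha, 1)

  expect_error(
    fit_switching_grid(obs, alpha_grid = 50, beta_grid = 0.005,
                       gamma_grid = 0, k_grid = 0.001, dt = 0.1, m0 = 4),
    class = "phenoswitch_fit_error")
})

test_that("observation tables are validated before fitting", {
  expect_error(
    fit_switching_grid(tibble::tibble(time_h = 12, fraction_small = 0.1),
                       1, 0.005, 0, 0.001),
    class = "phenoswitch_validation_error")
  expect_error(
    fit_switching_grid(
      tibble::tibble(time_h = c(12, 24), fraction_small = c(0.1, 1.2)),
      1, 0.005, 0, 0.001),
    class = "phenoswitch_validation_error")
  # counts are accepted in place of fractions
  obs <- tibble::tibble(time_h = c(12, 24, 48),
                        count_small = c(100, 200, 400),
                        count_large = c(9900, 9800, 9600))
  fit <- fit_switching_grid(obs, 1, c(0.001, 0.005), 0, 0.001, dt = 0.05)
  expect_s3_class(fit, "switching_fit")
})

test_that("tidy and glance expose the grid table and fit summary", {
  g <- default_grids()
  obs <- generate_timecourse_observations(
    switching_params(), observation_design(binomial_sampling = FALSE,
                                           seed = 2), dt = 0.05)
  fit <- fit_switching_grid(obs, g$alpha, g$beta, g$gamma, g$k, dt = 0.05)
  td <- tidy(fit)
  expect_equal(nrow(td), 3 * 3 * 2 * 3)
  expect_named(td, c("alpha", "beta", "gamma", "k", "objective"))
  gl <- glance(fit)
  expect_equal(gl$objective, fit$objective_best)
  expect_lte(gl$r_squared, 1)
  expect_equal(nrow(fit$residuals), 4)
  expect_equal(fit$residuals$residual,
               fit$residuals$observed - fit$residuals$predicted)
})
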