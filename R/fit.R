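#' Fit the switching model to phenotype proportions by grid search
#'
#' Evaluates every tuple `(alpha, beta, gamma, k)` on the Cartesian grid,
#' simulating the model deterministically (`sigma_eta = 0`) and scoring it
#' by the prediction error: the RMSE between predicted and observed
#' small-cluster fractions across the observation times. The best tuple is
#' the grid argmin; ties break lexicographically by `(alpha, beta, gamma,
#' k)` ascending. A tuple whose simulation fails (e.g. step-size
#' instability) scores an infinite objective rather than aborting the
#' search.
#'
#' @param observations A tibble with columns `time_h` and `fraction_small`
#'   (or `count_small`/`count_large`, from which the fraction is derived);
#'   at least 2 timepoints with fractions in `[0, 1]`.
#' @param alpha_grid,beta_grid,gamma_grid,k_grid Non-empty numeric vectors
#'   of candidate values (sorted internally).
#' @param t_end Simulation horizon, hours; defaults to the last
#'   observation time.
#' @param dt Euler step, hours.
#' @param t_switch Sigmoid midpoint, hours (held fixed across the grid).
#' @param m0,u0 Initial abundances, held fixed across the grid.
#'
#' @return An object of class `switching_fit` with `best_params`
#'   ([switching_params()]), `objective_best` (RMSE of fractions),
#'   `grid_table` (every tuple with its objective), `r_squared` of
#'   predicted vs observed percentages, per-timepoint `residuals`
#'   (observed - predicted fractions) and `residual_sd`. `tidy()` returns
#'   the grid table; `glance()` the one-row fit summary.
#' @examples
#' obs <- generate_timecourse_observations(
#'   switching_params(alpha = 1, beta = 0.005),
#'   observation_design(binomial_sampling = FALSE))
#' fit <- fit_switching_grid(obs,
#'   alpha_grid = c(0.5, 1), beta_grid = c(0.005, 0.02),
#'   gamma_grid = 0, k_grid = c(0.001, 0.1))
#' glance(fit)
#' @export
fit_switching_grid <- function(observations,
                               alpha_grid, beta_grid, gamma_grid, k_grid,
                               t_end = NULL, dt = 0.01, t_switch = 20,
                               m0 = 2, u0 = 0) {
  obs <- .observation_fractions(observations)
  if (nrow(obs) < 2) {
    abort("Grid fitting needs at least 2 observation timepoints.",
          class = "phenoswitch_validation_error")
  }
  if (any(obs$fraction_small < 0 | obs$fraction_small > 1)) {
    abort("Observed fractions must lie in [0, 1].",
          class = "phenoswitch_validation_error")
  }
  for (g in list(alpha_grid, beta_grid, gamma_grid, k_grid)) {
    if (length(g) < 1 || anyNA(g)) {
      abort("Parameter grids must be non-empty and free of NA.",
            class = "phenoswitch_validation_error")
    }
  }
  if (is.null(t_end)) t_end <- max(obs$time_h)

  # expand_grid varies the last column fastest, so with sorted grids the
  # rows are already in (alpha, beta, gamma, k) lexicographic order and
  # which.min's first-match rule implements the tie-break.
  grid <- tidyr::expand_grid(
    alpha = sort(unique(alpha_grid)),
    beta = sort(unique(beta_grid)),
    gamma = sort(unique(gamma_grid)),
    k = sort(unique(k_grid))
  )

  predict_tuple <- function(alpha, beta, gamma, k) {
    params <- switching_params(alpha = alpha, beta = beta, gamma = gamma,
                               k = k, t_switch = t_switch, sigma_eta = 0,
                               m0 = m0, u0 = u0)
    traj <- simulate_switching(params, t_end = t_end, dt = dt)
    predicted_fractions(traj, obs$time_h)
  }

  objectives <- purrr::pmap_dbl(grid, function(alpha, beta, gamma, k) {
    tryCatch({
      pred <- predict_tuple(alpha, beta, gamma, k)
      sqrt(mean((pred - obs$fraction_small)^2))
    }, error = function(e) Inf)
  })

  if (all(!is.finite(objectives))) {
    abort("Every grid tuple failed to simulate; no fit possible.",
          class = "phenoswitch_fit_error")
  }

  grid$objective <- objectives
  best_i <- which.min(objectives)
  best <- grid[best_i, ]
  best_params <- switching_params(
    alpha = best$alpha, beta = best$beta, gamma = best$gamma, k = best$k,
    t_switch = t_switch, sigma_eta = 0, m0 = m0, u0 = u0
  )
  pred_best <- predict_tuple(best$alpha, best$beta, best$gamma, best$k)

  gof <- tryCatch(
    goodness_of_fit(100 * obs$fraction_small, 100 * pred_best),
    error = function(e) tibble(r_squared = NA_real_, residual_sd = NA_real_)
  )
  residuals <- tibble(
    time_h = obs$time_h,
    observed = obs$fraction_small,
    predicted = pred_best,
    residual = obs$fraction_small - pred_best
  )

  structure(
    list(
      best_params = best_params,
      objective_best = best$objective,
      grid_table = grid,
      r_squared = gof$r_squared,
      residuals = residuals,
      residual_sd = sd(residuals$residual),
      t_end = t_end, dt = dt
    ),
    class = "switching_fit"
  )
}

.observation_fractions <- function(observations) {
  .require_columns(observations, "time_h", "observation table")
  obs <- as_tibble(observations)
  if (!"fraction_small" %in% names(obs)) {
    .require_columns(obs, c("count_small", "count_large"),
                     "observation table")
    obs$fraction_small <- obs$count_small /
      (obs$count_small + obs$count_large)
  }
  obs[, c("time_h", "fraction_small")]
}

#' @export
print.switching_fit <- function(x, ...) {
  p <- x$best_params
  cat("<switching_fit>", nrow(x$grid_table), "grid tuples evaluated\n")
  cat(sprintf("  best: alpha = %g, beta = %g, gamma = %g, k = %g\n",
              p$alpha, p$beta, p$gamma, p$k))
  cat(sprintf("  objective (RMSE of fractions) = %.4g, R^2 = %.4f, residual SD = %.4g\n",
              x$objective_best, x$r_squared, x$residual_sd))
  invisible(x)
}

#' Tidy a grid-search fit
#'
#' @param x A `switching_fit`.
#' @param ... Unused.
#' @return `tidy()` gives the full grid table (one row per evaluated
#'   tuple, with its RMSE objective); `glance()` gives a one-row summary
#'   with the best tuple, objective, `r_squared` and `residual_sd`.
#' @method tidy switching_fit
#' @export
tidy.switching_fit <- function(x, ...) x$grid_table

#' @rdname tidy.switching_fit
#' @method glance switching_fit
#' @export
glance.switching_fit <- function(x, ...) {
  p <- x$best_params
  tibble(
    alpha = p$alpha, beta = p$beta, gamma = p$gamma, k = p$k,
    t_switch = p$t_switch,
    objective = x$objective_best,
    r_squared = x$r_squared,
    residual_sd = x$residual_sd,
    n_grid = nrow(x$grid_table)
  )
}
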