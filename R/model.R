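#' Parameters of the two-phenotype switching model
#'
#' The population holds two phenotypes: large multicellular clusters `M`
#' and small ancestral-like clusters `U`. Large clusters grow (by
#' fragmentation into two clusters) at rate `alpha * log2(M)` with optional
#' additive noise; small clusters are shed from large ones at rate `beta`,
#' gated by a sigmoid switch `S(t)` that activates around the post-diauxic
#' transition; `gamma` is the rate at which small clusters revert to large
#' ones:
#'
#' \deqn{dM/dt = \alpha \log_2(M) + \eta(t) + \gamma U}
#' \deqn{dU/dt = S(t)\,\beta\,M - \gamma U}
#'
#' @param alpha Growth-rate coefficient of large clusters, per hour.
#' @param beta Small-cluster production rate from large clusters, per hour.
#' @param gamma Reversion rate of small clusters into large ones, per hour
#'   (0 in the best-fit regime: small clusters persist).
#' @param k Sigmoid steepness of the switch, per hour.
#' @param t_switch Sigmoid midpoint, hours (default 20, the onset of the
#'   post-diauxic growth phase).
#' @param sigma_eta SD scale of the growth fluctuation term `eta(t)`
#'   (same units as `dM/dt`); 0 gives a fully deterministic model.
#' @param m0,u0 Initial abundances. `m0` must exceed 1 (at `M = 1` the
#'   `log2` growth term vanishes, a fixed point), `u0` must be
#'   non-negative.
#'
#' @return An object of class `switching_params`.
#' @examples
#' switching_params(alpha = 1, beta = 0.005, gamma = 0, k = 0.001)
#' @export
switching_params <- function(alpha = 1, beta = 0.005, gamma = 0, k = 0.001,
                             t_switch = 20, sigma_eta = 0, m0 = 2, u0 = 0) {
  vals <- c(alpha = alpha, beta = beta, gamma = gamma, k = k,
            sigma_eta = sigma_eta)
  if (anyNA(vals) || any(vals < 0)) {
    abort("alpha, beta, gamma, k and sigma_eta must be non-negative.",
          class = "phenoswitch_validation_error")
  }
  if (!is.numeric(m0) || m0 <= 1) {
    abort("`m0` must exceed 1 (M = 1 is a fixed point of the growth term).",
          class = "phenoswitch_validation_error")
  }
  if (u0 < 0) {
    abort("`u0` must be non-negative.",
          class = "phenoswitch_validation_error")
  }
  structure(
    list(alpha = alpha, beta = beta, gamma = gamma, k = k,
         t_switch = t_switch, sigma_eta = sigma_eta, m0 = m0, u0 = u0),
    class = "switching_params"
  )
}

#' Coerce a list (e.g. parsed YAML) to switching parameters
#'
#' @param x A named list with any subset of the [switching_params()]
#'   fields; missing fields take the defaults.
#' @return A `switching_params` object.
#' @export
as_switching_params <- function(x) {
  if (inherits(x, "switching_params")) return(x)
  stopifnot(is.list(x))
  known <- names(formals(switching_params))
  extra <- setdiff(names(x), known)
  if (length(extra) > 0) {
    abort(paste0("Unknown switching parameter(s): ",
                 paste(extra, collapse = ", ")),
          class = "phenoswitch_validation_error")
  }
  do.call(switching_params, x)
}

#' @export
print.switching_params <- function(x, ...) {
  cat("<switching_params>\n")
  cat(sprintf("  alpha = %g /h, beta = %g /h, gamma = %g /h\n",
              x$alpha, x$beta, x$gamma))
  cat(sprintf("  switch: k = %g /h, midpoint = %g h\n", x$k, x$t_switch))
  cat(sprintf("  noise sigma_eta = %g; M(0) = %g, U(0) = %g\n",
              x$sigma_eta, x$m0, x$u0))
  invisible(x)
}

#' Sigmoid switch probability
#'
#' Probability that the stochastic large-to-small switch is active at time
#' `t`: the logistic curve `S(t) = 1 / (1 + exp(-k (t - t_switch)))`.
#' Strictly increasing in `t` for `k > 0`, flat at 0.5 for `k = 0`, and
#' saturating without overflow at extreme arguments.
#'
#' @param t Time, hours (vectorized).
#' @param k Steepness, per hour (non-negative).
#' @param t_switch Midpoint, hours: `S(t_switch) = 0.5`.
#' @return Probabilities in `[0, 1]`.
#' @examples
#' sigmoid_switch(20, k = 0.1, t_switch = 20)
#' @export
sigmoid_switch <- function(t, k, t_switch = 20) {
  if (any(k < 0)) {
    abort("`k` must be non-negative.",
          class = "phenoswitch_validation_error")
  }
  plogis(k * (t - t_switch))
}

#' Simulate the switching model
#'
#' Explicit Euler integration of the two-phenotype dynamics on a uniform
#' grid; the growth fluctuation `eta(t)` enters Euler--Maruyama style,
#' contributing `sigma_eta * sqrt(dt) * z` with `z` a standard normal draw
#' per step (none when `sigma_eta = 0`, in which case the run is fully
#' deterministic and `seed` is ignored). After every step `M` is floored at
#' `1 + 1e-9` (the growth term's fixed point) and `U` at 0; a step that
#' changes `M` by more than 50% aborts with a step-size error.
#'
#' @param params A [switching_params()] object.
#' @param t_end Final time, hours.
#' @param dt Euler step, hours, in `(0, 0.1]`.
#' @param seed Integer seed for the noise draws, or `NULL` to use the
#'   current RNG state. Ignored when `sigma_eta = 0`.
#'
#' @return A `switching_trajectory`: a tibble with columns `time_h`, `M`,
#'   `U` and `fraction_small = U / (U + M)`, one row per grid node
#'   including `t = 0`.
#' @examples
#' traj <- simulate_switching(switching_params(), t_end = 48)
#' predicted_fractions(traj, c(12, 20, 24, 48))
#' @export
simulate_switching <- function(params, t_end = 48, dt = 0.01, seed = NULL) {
  stopifnot(inherits(params, "switching_params"))
  if (!(dt > 0 && dt <= 0.1)) {
    abort("`dt` must lie in (0, 0.1].",
          class = "phenoswitch_validation_error")
  }
  if (t_end < dt) {
    abort("`t_end` must be at least one step `dt`.",
          class = "phenoswitch_validation_error")
  }
  n <- as.integer(round(t_end / dt))
  times <- (0:n) * dt
  m_floor <- 1 + 1e-9

  stochastic <- params$sigma_eta > 0
  noise <- if (stochastic) {
    draw <- function() params$sigma_eta * sqrt(dt) * rnorm(n)
    if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  } else {
    numeric(n)
  }

  s_left <- sigmoid_switch(times[1:n], params$k, params$t_switch)
  M <- numeric(n + 1)
  U <- numeric(n + 1)
  M[1] <- params$m0
  U[1] <- params$u0
  alpha <- params$alpha; beta <- params$beta; gamma <- params$gamma
  for (i in 1:n) {
    m <- M[i]; u <- U[i]
    dm <- alpha * log2(m) + gamma * u
    du <- s_left[i] * beta * m - gamma * u
    m_new <- m + dt * dm + noise[i]
    u_new <- u + dt * du
    if (abs(m_new - m) > 0.5 * m) {
      abort(sprintf(
        "Integration unstable at t = %.3f h: M changed by more than 50%% in one step; reduce dt.",
        times[i]), class = "phenoswitch_step_error")
    }
    M[i + 1] <- max(m_new, m_floor)
    U[i + 1] <- max(u_new, 0)
  }

  out <- tibble(time_h = times, M = M, U = U,
                fraction_small = U / (U + M))
  attr(out, "params") <- params
  attr(out, "dt") <- dt
  class(out) <- c("switching_trajectory", class(out))
  out
}

#' Interpolate the small-cluster fraction at observation times
#'
#' @param traj A [simulate_switching()] trajectory.
#' @param observation_times Times in hours, each within the simulated
#'   range.
#' @return Numeric vector of linearly interpolated `fraction_small`
#'   values; a time on a grid node returns the grid value exactly.
#' @export
predicted_fractions <- function(traj, observation_times) {
  .require_columns(traj, c("time_h", "fraction_small"), "trajectory")
  rng <- range(traj$time_h)
  out_of_range <- observation_times < rng[1] | observation_times > rng[2]
  if (any(out_of_range)) {
    abort(sprintf(
      "Observation time %g h outside the simulated range [%g, %g] h.",
      observation_times[which(out_of_range)[1]], rng[1], rng[2]),
      class = "phenoswitch_range_error")
  }
  approx(traj$time_h, traj$fraction_small, xout = observation_times,
         method = "linear", ties = "ordered")$y
}

#' Goodness of fit of predicted phenotype fractions
#'
#' Coefficient of determination `R^2 = 1 - SS_res / SS_tot` (total sum of
#' squares about the observed mean) together with the sample SD of the
#' residuals `observed - predicted`. `R^2` is 1 for a perfect fit and 0
#' when the prediction does no better than the observed mean; it is
#' identical whether computed on fractions or on percentages.
#'
#' @param observed,predicted Equal-length numeric vectors (length >= 2).
#' @return A one-row tibble with `r_squared` and `residual_sd`.
#' @examples
#' goodness_of_fit(c(0.2, 0.4, 0.6), c(0.25, 0.35, 0.65))
#' @export
goodness_of_fit <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2) {
    abort("`observed` and `predicted` must have equal length >= 2.",
          class = "phenoswitch_validation_error")
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    abort("R-squared is undefined for constant observations (SS_tot = 0).",
          class = "phenoswitch_degenerate_error")
  }
  res <- observed - predicted
  tibble(
    r_squared = 1 - sum(res^2) / ss_tot,
    residual_sd = sd(res)
  )
}
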