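#' Fit a two-component Gaussian mixture to particle diameters
#'
#' Decomposes a diameter distribution into its small- and large-cluster
#' subpopulations by expectation-maximization on a univariate two-component
#' normal mixture, and fits the one-component (single Gaussian) model in
#' closed form alongside for model selection.
#'
#' Initialization is deterministic: component means at the 25th and 75th
#' sample quantiles, both SDs at the overall sample SD, equal weights.
#' Components in the result are sorted by mean (ties by SD). Component SDs
#' are floored at `1e-6` um to prevent likelihood singularities; if the
#' floor ever engages, the fit is flagged via `sd_floored`.
#'
#' @param data A particle tibble with a `diameter_um` column, or a numeric
#'   vector of diameters. At least 10 values with nonzero variance.
#' @param tol Convergence tolerance on the log-likelihood increment.
#' @param max_iter Maximum EM iterations; if the tolerance is not reached,
#'   `converged` is `FALSE`.
#'
#' @return An object of class `mixture_fit`: weights, means and SDs of the
#'   sorted components, log-likelihoods and BICs of the 2- and 1-component
#'   models, the per-iteration log-likelihood trace (`ll_trace`, which is
#'   non-decreasing), `n_iterations`, `converged` and `sd_floored`.
#' @seealso [bimodality_decision()], [tidy.mixture_fit()]
#' @examples
#' d <- generate_mixture_sample(mixture_spec(), n = 2000, seed = 3)
#' fit <- fit_two_component_mixture(d)
#' glance(fit)
#' @export
fit_two_component_mixture <- function(data, tol = 1e-8, max_iter = 500) {
  x <- .diameter_vector(data)
  n <- length(x)
  if (n < 10) {
    abort("Mixture fitting needs at least 10 diameters.",
          class = "phenoswitch_degenerate_error")
  }
  if (sd(x) == 0) {
    abort("Mixture fitting needs nonzero variance (all values identical).",
          class = "phenoswitch_degenerate_error")
  }
  sd_floor <- 1e-6

  w <- c(0.5, 0.5)
  mu <- as.numeric(quantile(x, c(0.25, 0.75), names = FALSE))
  if (mu[1] == mu[2]) mu <- mu + c(-1, 1) * sd(x) / 2
  s <- rep(sd(x), 2)

  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  sd_floored <- FALSE
  iter <- 0

  while (iter < max_iter) {
    iter <- iter + 1
    d1 <- w[1] * dnorm(x, mu[1], s[1])
    d2 <- w[2] * dnorm(x, mu[2], s[2])
    tot <- d1 + d2
    ll <- sum(log(tot))
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    r1 <- d1 / tot
    r2 <- 1 - r1
    n1 <- sum(r1)
    n2 <- n - n1
    mu <- c(sum(r1 * x) / n1, sum(r2 * x) / n2)
    s <- c(sqrt(sum(r1 * (x - mu[1])^2) / n1),
           sqrt(sum(r2 * (x - mu[2])^2) / n2))
    if (any(s < sd_floor)) {
      sd_floored <- TRUE
      s <- pmax(s, sd_floor)
    }
    w <- c(n1, n2) / n
  }

  ord <- order(mu, s)
  w <- w[ord]; mu <- mu[ord]; s <- s[ord]

  ll2 <- sum(log(w[1] * dnorm(x, mu[1], s[1]) +
                 w[2] * dnorm(x, mu[2], s[2])))
  mu1 <- mean(x)
  s1 <- sqrt(mean((x - mu1)^2))
  ll1 <- sum(dnorm(x, mu1, s1, log = TRUE))

  structure(
    list(
      weight_small = w[1], weight_large = w[2],
      mean_small = mu[1], mean_large = mu[2],
      sd_small = s[1], sd_large = s[2],
      log_likelihood_2comp = ll2,
      log_likelihood_1comp = ll1,
      bic_2comp = 5 * log(n) - 2 * ll2,
      bic_1comp = 2 * log(n) - 2 * ll1,
      n_iterations = iter,
      converged = converged,
      sd_floored = sd_floored,
      ll_trace = ll_trace,
      n = n,
      data = x
    ),
    class = "mixture_fit"
  )
}

.diameter_vector <- function(data) {
  if (is.numeric(data)) return(as.numeric(data))
  .require_columns(data, "diameter_um", "particle table")
  as.numeric(data$diameter_um)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("<mixture_fit>", x$n, "particles,", x$n_iterations, "EM iterations",
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat(sprintf("  small: w = %.3f, mean = %.3f um, sd = %.3f um\n",
              x$weight_small, x$mean_small, x$sd_small))
  cat(sprintf("  large: w = %.3f, mean = %.3f um, sd = %.3f um\n",
              x$weight_large, x$mean_large, x$sd_large))
  cat(sprintf("  logLik 2-comp = %.2f (BIC %.1f), 1-comp = %.2f (BIC %.1f)\n",
              x$log_likelihood_2comp, x$bic_2comp,
              x$log_likelihood_1comp, x$bic_1comp))
  invisible(x)
}

#' Tidy a two-component mixture fit
#'
#' @param x A `mixture_fit` object.
#' @param ... Unused.
#' @return `tidy()` gives one row per component (weight, mean, SD);
#'   `glance()` gives a one-row model summary with log-likelihoods, BICs,
#'   the BIC difference favouring two components, iteration count and
#'   convergence flags.
#' @method tidy mixture_fit
#' @export
tidy.mixture_fit <- function(x, ...) {
  tibble(
    component = c("small", "large"),
    weight = c(x$weight_small, x$weight_large),
    mean = c(x$mean_small, x$mean_large),
    sd = c(x$sd_small, x$sd_large)
  )
}

#' @rdname tidy.mixture_fit
#' @method glance mixture_fit
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble(
    n = x$n,
    log_likelihood_2comp = x$log_likelihood_2comp,
    log_likelihood_1comp = x$log_likelihood_1comp,
    bic_2comp = x$bic_2comp,
    bic_1comp = x$bic_1comp,
    delta_bic = x$bic_1comp - x$bic_2comp,
    n_iterations = x$n_iterations,
    converged = x$converged,
    sd_floored = x$sd_floored
  )
}

#' Decide bimodality from mixture model selection
#'
#' A distribution is called bimodal when the two-component Gaussian mixture
#' beats the single Gaussian by more than `delta_bic_threshold` BIC points
#' (strictly): `bic_1comp - bic_2comp > delta_bic_threshold`. A difference
#' exactly at the threshold is unimodal.
#'
#' @param fit A converged [fit_two_component_mixture()] result.
#' @param delta_bic_threshold BIC margin required to declare bimodality
#'   (default 10, conventional "very strong" evidence).
#' @return `"bimodal"` or `"unimodal"`.
#' @export
bimodality_decision <- function(fit, delta_bic_threshold = 10) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (!fit$converged) {
    abort(paste0("Mixture fit did not converge after ", fit$n_iterations,
                 " iterations; refusing a bimodality decision. ",
                 "Increase max_iter or relax tol."),
          class = "phenoswitch_convergence_error")
  }
  if (fit$bic_1comp - fit$bic_2comp > delta_bic_threshold) "bimodal"
  else "unimodal"
}
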