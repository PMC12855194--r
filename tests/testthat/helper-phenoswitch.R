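# Shared fixtures, built in code.

# Well-separated reference mixture: 4-sigma separation between modes,
# effectively untruncated (threshold far below both modes).
separated_spec <- function(threshold = 0) {
  mixture_spec(weight_small = 0.5, mean_small = 5, sd_small = 1,
               mean_large = 25, sd_large = 5,
               detection_threshold = threshold)
}

# Raw (untruncated) mixture density/CDF written out with dnorm/pnorm so the
# tests' reference distribution is independent of the package's own
# dmixture/pmixture helpers.
ref_mix_density <- function(x, spec) {
  spec$weight_small * dnorm(x, spec$mean_small, spec$sd_small) +
    (1 - spec$weight_small) * dnorm(x, spec$mean_large, spec$sd_large)
}
ref_mix_cdf <- function(x, spec) {
  spec$weight_small * pnorm(x, spec$mean_small, spec$sd_small) +
    (1 - spec$weight_small) * pnorm(x, spec$mean_large, spec$sd_large)
}

# Moments of the left-truncated mixture by quadrature.
ref_truncated_moment <- function(spec, power = 1) {
  thr <- spec$detection_threshold
  mass <- 1 - ref_mix_cdf(thr, spec)
  upper <- spec$mean_large + 12 * spec$sd_large
  stats::integrate(function(x) x^power * ref_mix_density(x, spec) / mass,
                   lower = thr, upper = upper,
                   rel.tol = 1e-10)$value
}

# Hand-rolled mixture_fit skeleton for boundary tests.
fake_mixture_fit <- function(bic_1comp, bic_2comp, converged = TRUE) {
  structure(
    list(weight_small = 0.5, weight_large = 0.5,
         mean_small = 5, mean_large = 25, sd_small = 1, sd_large = 5,
         log_likelihood_2comp = 0, log_likelihood_1comp = 0,
         bic_2comp = bic_2comp, bic_1comp = bic_1comp,
         n_iterations = 1, converged = converged, sd_floored = FALSE,
         ll_trace = 0, n = 100, data = numeric(0)),
    class = "mixture_fit"
  )
}

# Default parameter grids used by the round-trip fitting tests: the
# printed best-fit tuple sits inside, never at a degenerate corner.
default_grids <- function() {
  list(alpha = c(0.5, 1, 2),
       beta = c(0.001, 0.005, 0.02),
       gamma = c(0, 0.01),
       k = c(0.001, 0.1, 1))
}
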