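#' Specify a two-component Gaussian diameter mixture
#'
#' Describes the bimodal particle-diameter distribution of a bistable
#' multicellular yeast population: a small-propagule mode (roughly 3--13 um)
#' and a large-cluster mode (> 13 um), left-truncated at the instrument's
#' lower detection threshold.
#'
#' @param weight_small Mixing proportion of the small-diameter component,
#'   in `[0, 1]`.
#' @param mean_small,sd_small Mean and standard deviation of the small
#'   component, in um. `sd_small` must be positive.
#' @param mean_large,sd_large Mean and standard deviation of the large
#'   component, in um. Must satisfy `mean_small < mean_large`.
#' @param detection_threshold Lower detection limit of the instrument, in um
#'   (non-negative). Generated diameters strictly exceed it.
#'
#' @details The defaults (modes at 6 and 25 um, SDs 1.5 and 5 um, threshold
#' 3 um) place essentially all small-mode mass below and all large-mode mass
#' above the 13 um class boundary used throughout the package. They are
#' generator conventions, not measured values.
#'
#' @return An object of class `mixture_spec`.
#' @examples
#' spec <- mixture_spec()
#' particles <- generate_mixture_sample(spec, n = 500, seed = 1)
#' @export
mixture_spec <- function(weight_small = 0.5, mean_small = 6, sd_small = 1.5,
                         mean_large = 25, sd_large = 5,
                         detection_threshold = 3) {
  if (!is.numeric(weight_small) || length(weight_small) != 1 ||
      is.na(weight_small) || weight_small < 0 || weight_small > 1) {
    abort("`weight_small` must be a single number in [0, 1].",
          class = "phenoswitch_validation_error")
  }
  if (sd_small <= 0 || sd_large <= 0) {
    abort("Component standard deviations must be positive.",
          class = "phenoswitch_validation_error")
  }
  if (mean_small >= mean_large) {
    abort("`mean_small` must be strictly less than `mean_large`.",
          class = "phenoswitch_validation_error")
  }
  if (detection_threshold < 0) {
    abort("`detection_threshold` must be non-negative.",
          class = "phenoswitch_validation_error")
  }
  structure(
    list(weight_small = weight_small, mean_small = mean_small,
         sd_small = sd_small, mean_large = mean_large, sd_large = sd_large,
         detection_threshold = detection_threshold),
    class = "mixture_spec"
  )
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat("<mixture_spec>\n")
  cat(sprintf("  small: w = %.3f, N(%.3g, %.3g) um\n",
              x$weight_small, x$mean_small, x$sd_small))
  cat(sprintf("  large: w = %.3f, N(%.3g, %.3g) um\n",
              1 - x$weight_small, x$mean_large, x$sd_large))
  cat(sprintf("  detection threshold: %.3g um\n", x$detection_threshold))
  invisible(x)
}

#' Mixture density of diameters, truncated at the detection threshold
#'
#' Density and distribution function of the left-truncated two-component
#' Gaussian mixture described by a [mixture_spec()]. Used by the generator
#' tests as the analytic reference distribution.
#'
#' @param x Vector of diameters (um).
#' @param spec A [mixture_spec()].
#' @return A numeric vector of densities (`dmixture`) or cumulative
#'   probabilities (`pmixture`); zero below the detection threshold.
#' @export
dmixture <- function(x, spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  raw <- spec$weight_small * dnorm(x, spec$mean_small, spec$sd_small) +
    (1 - spec$weight_small) * dnorm(x, spec$mean_large, spec$sd_large)
  mass <- 1 - .pmix_raw(spec$detection_threshold, spec)
  ifelse(x > spec$detection_threshold, raw / mass, 0)
}

#' @rdname dmixture
#' @export
pmixture <- function(x, spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  thr <- spec$detection_threshold
  p_thr <- .pmix_raw(thr, spec)
  p <- (.pmix_raw(x, spec) - p_thr) / (1 - p_thr)
  pmin(pmax(ifelse(x > thr, p, 0), 0), 1)
}

.pmix_raw <- function(x, spec) {
  spec$weight_small * pnorm(x, spec$mean_small, spec$sd_small) +
    (1 - spec$weight_small) * pnorm(x, spec$mean_large, spec$sd_large)
}

#' Generate a synthetic particle-diameter sample
#'
#' Draws diameters from the two-component Gaussian mixture of `spec`,
#' rejecting draws at or below the detection threshold (the instrument
#' cannot register them). Emulates one Coulter-counter export for one
#' strain/timepoint.
#'
#' @param spec A [mixture_spec()].
#' @param n Number of particles to generate (non-negative).
#' @param seed Integer seed; identical seeds give bitwise-identical samples.
#'   The caller's RNG state is untouched.
#' @param sample_id,time_h Metadata attached to every row.
#'
#' @return A tibble with columns `sample_id`, `time_h`, `diameter_um`, with
#'   the detection threshold stored in attribute `"detection_threshold"`.
#' @examples
#' d <- generate_mixture_sample(mixture_spec(), n = 1000, seed = 42)
#' classify_particles(d)
#' @export
generate_mixture_sample <- function(spec, n, seed,
                                    sample_id = "synthetic", time_h = 24) {
  stopifnot(inherits(spec, "mixture_spec"))
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 0 || n != floor(n)) {
    abort("`n` must be a single non-negative integer.",
          class = "phenoswitch_validation_error")
  }
  n <- as.integer(n)
  diam <- withr::with_seed(seed, .rmix_truncated(n, spec))
  out <- tibble(
    sample_id = rep(as.character(sample_id), n),
    time_h = rep(as.numeric(time_h), n),
    diameter_um = diam
  )
  attr(out, "detection_threshold") <- spec$detection_threshold
  out
}

.rmix_truncated <- function(n, spec) {
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(n - length(out), 16L)
    comp <- runif(m) < spec$weight_small
    x <- ifelse(comp,
                rnorm(m, spec$mean_small, spec$sd_small),
                rnorm(m, spec$mean_large, spec$sd_large))
    out <- c(out, x[x > spec$detection_threshold])
  }
  out[seq_len(n)]
}

#' Define a time-course observation design
#'
#' When and how intensively phenotype counts are taken. The default
#' observation times 12, 20, 24 and 48 h match the growth-cycle sampling
#' scheme the model is assessed against.
#'
#' @param observation_times Strictly increasing vector of observation times
#'   in hours.
#' @param total_count_per_time Particles tallied per observation time
#'   (positive integer).
#' @param binomial_sampling If `TRUE`, small-cluster counts are drawn as
#'   `Binomial(total_count_per_time, fraction_small)`; if `FALSE` the
#'   deterministic model fractions are passed through exactly.
#' @param seed Integer seed governing all randomness of the observation
#'   process (trajectory noise and binomial draws).
#'
#' @return An object of class `observation_design`.
#' @export
observation_design <- function(observation_times = c(12, 20, 24, 48),
                               total_count_per_time = 10000,
                               binomial_sampling = TRUE, seed = 1) {
  if (length(observation_times) < 1 || anyNA(observation_times) ||
      any(diff(observation_times) <= 0)) {
    abort("`observation_times` must be strictly increasing.",
          class = "phenoswitch_validation_error")
  }
  if (total_count_per_time < 1 ||
      total_count_per_time != floor(total_count_per_time)) {
    abort("`total_count_per_time` must be a positive integer.",
          class = "phenoswitch_validation_error")
  }
  structure(
    list(observation_times = as.numeric(observation_times),
         total_count_per_time = as.integer(total_count_per_time),
         binomial_sampling = isTRUE(binomial_sampling),
         seed = as.integer(seed)),
    class = "observation_design"
  )
}

#' Generate phenotype-count observations from the switching model
#'
#' Simulates the two-phenotype switching model forward and emulates particle
#' counting at each observation time: the fraction of small clusters is read
#' off the trajectory and, when `binomial_sampling` is on, the small-cluster
#' tally is a binomial draw at that fraction.
#'
#' @param params A [switching_params()] object (set `sigma_eta > 0` for
#'   growth noise in the underlying trajectory).
#' @param design An [observation_design()].
#' @param dt Euler step of the underlying simulation, hours.
#'
#' @return A tibble with columns `time_h`, `count_small`, `count_large`,
#'   `fraction_small`. With `binomial_sampling = FALSE` the
#'   `fraction_small` column carries the deterministic model fractions
#'   exactly; otherwise it is `count_small / total_count_per_time`.
#' @examples
#' obs <- generate_timecourse_observations(
#'   switching_params(), observation_design(seed = 7))
#' @export
generate_timecourse_observations <- function(params, design, dt = 0.01) {
  stopifnot(inherits(params, "switching_params"),
            inherits(design, "observation_design"))
  t_end <- max(design$observation_times)
  withr::with_seed(design$seed, {
    traj <- simulate_switching(params, t_end = t_end, dt = dt, seed = NULL)
    frac <- predicted_fractions(traj, design$observation_times)
    n_tot <- design$total_count_per_time
    if (design$binomial_sampling) {
      count_small <- rbinom(length(frac), n_tot, frac)
      fraction <- count_small / n_tot
    } else {
      count_small <- as.integer(round(n_tot * frac))
      fraction <- frac
    }
    tibble(
      time_h = design$observation_times,
      count_small = as.integer(count_small),
      count_large = n_tot - as.integer(count_small),
      fraction_small = fraction
    )
  })
}

#' Write and read particle and observation tables
#'
#' Plain-CSV serialization: particle tables with columns `sample_id`,
#' `time_h`, `diameter_um`; observation tables with columns `time_h`,
#' `count_small`, `count_large`, `fraction_small`. UTF-8, header row,
#' `.` decimal separator.
#'
#' @param data A tibble as produced by [generate_mixture_sample()] or
#'   [generate_timecourse_observations()].
#' @param path File path.
#' @return `data`, invisibly.
#' @export
write_particle_csv <- function(data, path) {
  .require_columns(data, c("sample_id", "time_h", "diameter_um"),
                   "particle table")
  readr::write_csv(data[, c("sample_id", "time_h", "diameter_um")], path)
  invisible(data)
}

#' @rdname write_particle_csv
#' @export
write_observation_csv <- function(data, path) {
  .require_columns(data, c("time_h", "count_small", "count_large",
                           "fraction_small"), "observation table")
  readr::write_csv(data, path)
  invisible(data)
}

#' @rdname write_particle_csv
#' @export
read_observation_csv <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Observation file not found: ", path),
          class = "phenoswitch_io_error")
  }
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  .require_columns(out, c("time_h", "count_small", "count_large",
                          "fraction_small"), "observation table")
  as_tibble(out)
}

.require_columns <- function(data, cols, what) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(paste0("Missing column(s) in ", what, ": ",
                 paste(missing, collapse = ", ")),
          class = "phenoswitch_parse_error")
  }
  invisible(data)
}
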