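#' Build a pipeline configuration
#'
#' One configuration object drives the whole analysis: particle input
#' (a CSV path or a synthetic specification), observation input (CSV path
#' or synthetic), mixture/overlap/classification settings, the model grid,
#' an output directory and a master seed. Exactly one of `input` /
#' `synthetic` must be given per data stage.
#'
#' Per-stage seeds are derived from the master seed by a fixed counter
#' scheme: particle sample `i` uses `seed + i`, the observation stage uses
#' `seed + 1000`. This keeps every stochastic stage reproducible in
#' isolation.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Master seed (integer).
#' @param particles A list with either `input` (CSV path) or `synthetic`
#'   (a list with optional [mixture_spec()] fields, `n_per_sample`, and a
#'   `samples` list of `sample_id` / `time_h` entries).
#' @param observations A list with either `input` (CSV path) or
#'   `synthetic` (a list with optional `params` for [switching_params()]
#'   and `observation_times`, `total_count_per_time`,
#'   `binomial_sampling`).
#' @param mixture List: `tol`, `max_iter`, `delta_bic_threshold`.
#' @param overlap List: `n_grid`.
#' @param classify List: `threshold` (um).
#' @param fit List: `alpha_grid`, `beta_grid`, `gamma_grid`, `k_grid`,
#'   plus optional `t_end`, `dt`, `t_switch`.
#'
#' @return An object of class `pipeline_config`.
#' @seealso [run_pipeline()], [read_pipeline_config()]
#' @export
pipeline_config <- function(out_dir, seed = 1,
                            particles = list(synthetic = list()),
                            observations = list(synthetic = list()),
                            mixture = list(), overlap = list(),
                            classify = list(), fit = list()) {
  .check_one_source(particles, "particles")
  .check_one_source(observations, "observations")
  mixture <- utils::modifyList(
    list(tol = 1e-8, max_iter = 500, delta_bic_threshold = 10), mixture)
  overlap <- utils::modifyList(list(n_grid = 1024), overlap)
  classify <- utils::modifyList(list(threshold = 13), classify)
  fit <- utils::modifyList(
    list(alpha_grid = c(0.5, 1, 2), beta_grid = c(0.001, 0.005, 0.02),
         gamma_grid = c(0, 0.01), k_grid = c(0.001, 0.1, 1),
         t_end = NULL, dt = 0.01, t_switch = 20), fit)
  # YAML sequences of mixed int/double arrive as lists; flatten them
  for (f in c("alpha_grid", "beta_grid", "gamma_grid", "k_grid")) {
    fit[[f]] <- as.numeric(unlist(fit[[f]]))
  }
  if (!is.null(fit$t_end)) fit$t_end <- as.numeric(fit$t_end)
  structure(
    list(out_dir = out_dir, seed = as.integer(seed),
         particles = particles, observations = observations,
         mixture = mixture, overlap = overlap, classify = classify,
         fit = fit),
    class = "pipeline_config"
  )
}

.check_one_source <- function(stage, name) {
  has <- c("input", "synthetic") %in% names(stage)
  if (sum(has) != 1) {
    abort(paste0("Stage '", name,
                 "' must have exactly one of `input` or `synthetic`."),
          class = "phenoswitch_validation_error")
  }
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose top-level keys match the
#'   arguments of [pipeline_config()].
#' @param out_dir,seed Optional overrides of the file's values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL, seed = NULL) {
  if (!file.exists(path)) {
    abort(paste0("Config file not found: ", path),
          class = "phenoswitch_io_error")
  }
  raw <- yaml::read_yaml(path)
  if (!is.null(out_dir)) raw$out_dir <- out_dir
  if (!is.null(seed)) raw$seed <- seed
  known <- names(formals(pipeline_config))
  do.call(pipeline_config, raw[intersect(names(raw), known)])
}

#' Run the full analysis pipeline
#'
#' Executes, in order: particle acquisition (synthetic generation or CSV
#' read), per-sample mixture fits and bimodality decisions, the pairwise
#' overlap matrix with Ward-D2 clustering (when 3+ samples), size-class
#' counts, observation acquisition, and the grid-search model fit. All
#' results are serialized under `config$out_dir` together with a run
#' manifest (config echo, seed, package version, per-stage wall time and
#' status, and an MD5 content hash for every output file) and a plain-text
#' summary. Identical config and seed give numerically identical outputs.
#'
#' On a stage failure the error is re-raised with the stage name, partial
#' outputs are kept, and the manifest records the stage as FAILED.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`particles`,
#'   `mixture_fits`, `overlap`, `clustering`, `size_classes`,
#'   `observations`, `fit`) and the `manifest`.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(out_dir = tempfile("run"), seed = 1)
#' res <- run_pipeline(cfg)
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  results <- list()
  stages <- list()
  run_stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e) {
      stages[[name]] <<- list(status = "FAILED",
                              message = conditionMessage(e),
                              wall_time_s = proc.time()[["elapsed"]] - t0)
      .write_manifest(config, stages, out)
      abort(paste0("Pipeline stage '", name, "' failed: ",
                   conditionMessage(e)),
            class = "phenoswitch_pipeline_error", parent = e)
    })
    stages[[name]] <<- list(status = "OK",
                            wall_time_s = proc.time()[["elapsed"]] - t0)
    res
  }

  # -- particles ------------------------------------------------------
  results$particles <- run_stage("particles", function() {
    p <- config$particles
    if (!is.null(p$input)) {
      particles <- read_particle_csv(p$input)
    } else {
      syn <- p$synthetic
      spec_fields <- intersect(names(syn), names(formals(mixture_spec)))
      spec <- do.call(mixture_spec, lapply(syn[spec_fields], as.numeric))
      n <- as.integer(syn$n_per_sample %||% 2000)
      samples <- syn$samples %||%
        list(list(sample_id = "synthetic", time_h = 20),
             list(sample_id = "synthetic", time_h = 24),
             list(sample_id = "synthetic", time_h = 48))
      particles <- purrr::imap(samples, function(s, i) {
        generate_mixture_sample(spec, n = n, seed = config$seed + i,
                                sample_id = s$sample_id,
                                time_h = s$time_h)
      }) |> purrr::list_rbind()
    }
    write_particle_csv(particles, out("particles.csv"))
    particles
  })

  # -- mixture fits + bimodality -------------------------------------
  results$mixture_fits <- run_stage("mixture", function() {
    cfg <- config$mixture
    groups <- .sample_groups(results$particles)
    fits <- purrr::map(groups, fit_two_component_mixture,
                       tol = cfg$tol, max_iter = cfg$max_iter)
    table <- purrr::imap(fits, function(f, label) {
      dplyr::bind_cols(
        tibble(sample = label),
        tibble(weight_small = f$weight_small,
               weight_large = f$weight_large,
               mean_small = f$mean_small, mean_large = f$mean_large,
               sd_small = f$sd_small, sd_large = f$sd_large),
        glance(f)[, c("log_likelihood_2comp", "log_likelihood_1comp",
                      "bic_2comp", "bic_1comp", "delta_bic",
                      "n_iterations", "converged")],
        tibble(decision = bimodality_decision(
          f, cfg$delta_bic_threshold))
      )
    }) |> purrr::list_rbind()
    readr::write_csv(table, out("mixture_fits.csv"))
    list(fits = fits, table = table)
  })

  # -- overlap + clustering ------------------------------------------
  results$overlap <- run_stage("overlap", function() {
    om <- overlap_matrix(results$particles,
                         n_grid = config$overlap$n_grid)
    readr::write_csv(
      cbind(tibble(sample = om$labels), as_tibble(om$eta)),
      out("overlap_matrix.csv"))
    om
  })
  results$clustering <- run_stage("clustering", function() {
    if (length(results$overlap$labels) < 3) return(NULL)
    cl <- cluster_overlap(results$overlap)
    readr::write_csv(tidy(cl), out("overlap_clustering.csv"))
    cl
  })

  # -- size classes ---------------------------------------------------
  results$size_classes <- run_stage("classify", function() {
    sc <- classify_particles(results$particles,
                             threshold = config$classify$threshold)
    readr::write_csv(sc, out("size_classes.csv"))
    sc
  })

  # -- observations ---------------------------------------------------
  results$observations <- run_stage("observations", function() {
    o <- config$observations
    if (!is.null(o$input)) {
      obs <- read_observation_csv(o$input)
    } else {
      syn <- o$synthetic
      params <- as_switching_params(syn$params %||% list())
      design <- observation_design(
        observation_times = as.numeric(unlist(
          syn$observation_times %||% c(12, 20, 24, 48))),
        total_count_per_time = syn$total_count_per_time %||% 10000,
        binomial_sampling = syn$binomial_sampling %||% TRUE,
        seed = config$seed + 1000
      )
      obs <- generate_timecourse_observations(params, design,
                                              dt = config$fit$dt)
    }
    write_observation_csv(obs, out("observations.csv"))
    obs
  })

  # -- model fit ------------------------------------------------------
  results$fit <- run_stage("fit", function() {
    cfg <- config$fit
    fit <- fit_switching_grid(
      results$observations,
      alpha_grid = cfg$alpha_grid, beta_grid = cfg$beta_grid,
      gamma_grid = cfg$gamma_grid, k_grid = cfg$k_grid,
      t_end = cfg$t_end, dt = cfg$dt, t_switch = cfg$t_switch
    )
    readr::write_csv(fit$grid_table, out("fit_grid_table.csv"))
    jsonlite::write_json(
      list(best_params = unclass(fit$best_params),
           objective_best = fit$objective_best,
           r_squared = fit$r_squared,
           residual_sd = fit$residual_sd,
           residuals = fit$residuals),
      out("fit.json"), auto_unbox = TRUE, digits = NA)
    fit
  })

  run_stage("report", function() {
    .write_summary(config, results, out("summary.txt"))
    NULL
  })
  results$manifest <- .write_manifest(config, stages, out)
  invisible(results)
}

.write_manifest <- function(config, stages, out) {
  files <- setdiff(list.files(config$out_dir), "manifest.json")
  paths <- file.path(config$out_dir, files)
  manifest <- list(
    package_version = as.character(utils::packageVersion("phenoswitch")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config = .config_echo(config),
    stages = stages,
    outputs = purrr::map2(files, paths, function(f, p) {
      list(file = f, md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest
}

.config_echo <- function(config) {
  x <- unclass(config)
  x$fit$t_end <- x$fit$t_end %||% NA
  x
}

.write_summary <- function(config, results, path) {
  mt <- results$mixture_fits$table
  sc <- results$size_classes
  fit <- results$fit
  p <- fit$best_params
  lines <- c(
    "phenoswitch pipeline summary",
    sprintf("seed: %d", config$seed),
    "",
    sprintf("particles: %d rows, %d samples", nrow(results$particles),
            nrow(mt)),
    sprintf("bimodal samples: %d / %d", sum(mt$decision == "bimodal"),
            nrow(mt)),
    sprintf("mean small-mode diameter: %.3f um; mean large-mode: %.3f um",
            mean(mt$mean_small), mean(mt$mean_large)),
    sprintf("overlap eta range (off-diagonal): %.3f - %.3f",
            min(tidy(results$overlap)$eta),
            max(tidy(results$overlap)$eta)),
    sprintf("fraction small (threshold %g um): %s",
            config$classify$threshold,
            paste(sprintf("%.3f", sc$fraction_small), collapse = ", ")),
    "",
    sprintf("model fit: alpha = %g, beta = %g, gamma = %g, k = %g",
            p$alpha, p$beta, p$gamma, p$k),
    sprintf("objective (RMSE) = %.6g, R^2 = %.4f, residual SD = %.6g",
            fit$objective_best, fit$r_squared, fit$residual_sd)
  )
  writeLines(lines, path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
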