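# End-to-end analysis pipeline: data in (measured CSV or synthetic), smooth
# curve fits, ComX model estimation and envelope, process metrics, assay
# summaries, productivity-vs-ComX curve. Every artifact is written to the
# output directory and listed, with a content hash, in manifest.yaml.

#' Pipeline configuration
#'
#' @param input_csv Path to a cultivation CSV, or `NULL` to generate
#'   synthetic data from `synth`.
#' @param synth A [synth_config()] used when `input_csv` is `NULL`.
#' @param conversion A [conversion_config()].
#' @param bounds Parameter bounds for the model fit ([comx_bounds()]).
#' @param ea0 Initial CSP activity for simulation and fitting.
#' @param envelope_frac Sensitivity-envelope perturbation (default 0.08).
#' @param blank_mean,blank_sd,blank_n Blank-set generation settings for the
#'   detection-limit stage (defaults: the shake-flask blank statistics).
#' @param seed Integer seed for every stochastic stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_csv = NULL, synth = synth_config(),
                            conversion = conversion_config(),
                            bounds = comx_bounds(), ea0 = 0,
                            envelope_frac = 0.08,
                            blank_mean = 15.84, blank_sd = 2.686,
                            blank_n = 20L, seed = 1L) {
  if (!is.null(input_csv) && !file.exists(input_csv)) {
    stop("input file not found: ", input_csv, call. = FALSE)
  }
  stopifnot(envelope_frac >= 0, envelope_frac < 1)
  structure(
    list(input_csv = input_csv, synth = synth, conversion = conversion,
         bounds = bounds, ea0 = ea0, envelope_frac = envelope_frac,
         blank_mean = blank_mean, blank_sd = blank_sd,
         blank_n = as.integer(blank_n), seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys mirror the [pipeline_config()] arguments;
#' `synth` and `conversion` may be nested maps of the respective
#' constructor arguments.
#'
#' @param path Path to a YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("input_csv", "ea0", "envelope_frac", "blank_mean", "blank_sd",
              "blank_n", "seed")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(y$synth)) args$synth <- do.call(synth_config, y$synth)
  if (!is.null(y$conversion)) {
    args$conversion <- do.call(conversion_config, y$conversion)
  }
  do.call(pipeline_config, args)
}

.write_yaml_report <- function(x, path) {
  yaml::write_yaml(lapply(x, function(v) if (is.numeric(v)) unname(v) else v),
                   path)
  path
}

#' Run the full analysis pipeline
#'
#' Stages: load or generate cultivation data; fit smooth curves to biomass,
#' surfactin and ComX of the first replicate; estimate the ComX model
#' parameters; simulate the fitted model and its sensitivity envelope;
#' compute per-replicate process metrics; compute bioassay detection limits
#' from a seeded blank set; derive the productivity-versus-ComX curve.
#' Each stage's artifacts are written as CSV/YAML; a failure retains the
#' completed artifacts and the manifest records which stages finished.
#'
#' @param config A [pipeline_config()] or path to a YAML config.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character()
  stages_done <- character()
  results <- list()
  add <- function(path) artifacts <<- c(artifacts, path)
  finish <- function() {
    manifest <- list(
      stages_completed = stages_done,
      seed = config$seed,
      package_version = as.character(utils::packageVersion("comxdyn")),
      artifacts = lapply(artifacts, function(p) {
        list(file = basename(p), md5 = unname(tools::md5sum(p)))
      })
    )
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
    manifest
  }

  run_stage <- function(name, expr) {
    message("stage: ", name)
    val <- tryCatch(expr, error = function(e) {
      finish()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    stages_done <<- c(stages_done, name)
    val
  }

  # data
  results$data <- run_stage("data", {
    if (is.null(config$input_csv)) {
      gen <- generate_cultivation(config$synth)
      p <- file.path(out_dir, "cultivation.csv")
      write_timeseries(gen$series, p); add(p)
      truth <- gen$truth
      tp <- file.path(out_dir, "truth.yaml")
      .write_yaml_report(list(
        biomass = unclass(truth$biomass_curve)[c("y0", "a", "t0", "tau")],
        surfactin = unclass(truth$surfactin_curve)[c("y0", "a", "t0", "tau")],
        comx_params = unclass(truth$params)[c("a0", "b", "d", "e", "f", "g")],
        ea0 = truth$ea0), tp)
      add(tp)
      gen
    } else {
      list(series = read_timeseries(config$input_csv, config$conversion),
           truth = NULL)
    }
  })
  series <- results$data$series
  rep1 <- tibble::as_tibble(series)
  rep1 <- rep1[rep1$replicate == rep1$replicate[1L], ]

  # curve fits
  results$fits <- run_stage("curvefit", {
    fits <- list(
      biomass = fit_sigmoid4(rep1$time_h, rep1$cdw_g_L),
      surfactin = fit_sigmoid4(rep1$time_h, rep1$surfactin_mg_L),
      comx = fit_sigmoid4(rep1$time_h, rep1$comx_MU)
    )
    p <- file.path(out_dir, "curve_fits.yaml")
    .write_yaml_report(lapply(fits, function(f)
      unclass(f)[c("y0", "a", "t0", "tau", "residual_sse")]), p)
    add(p)
    fits
  })

  # model estimation
  results$model_fit <- run_stage("estimation", {
    fit <- fit_comx_params(rep1, results$fits$biomass,
                           bounds = config$bounds, ea0 = config$ea0,
                           seed = config$seed)
    p <- file.path(out_dir, "comx_fit.yaml")
    .write_yaml_report(list(
      params = unclass(fit$params)[c("a0", "b", "d", "e", "f", "g")],
      sse = fit$sse, n_obs = fit$n_obs, converged = fit$converged,
      at_bounds = as.list(fit$at_bounds)), p)
    add(p)
    fit
  })

  # simulation + envelope
  results$envelope <- run_stage("simulate", {
    grid <- seq(min(rep1$time_h), max(rep1$time_h), length.out = 201)
    traj <- simulate_comx(results$model_fit$params, results$fits$biomass,
                          grid, ea0 = config$ea0)
    p1 <- file.path(out_dir, "trajectory.csv")
    write_trajectory(traj, p1); add(p1)
    env <- sensitivity_envelope(results$model_fit$params,
                                results$fits$biomass, grid,
                                frac = config$envelope_frac,
                                ea0 = config$ea0)
    p2 <- file.path(out_dir, "envelope.csv")
    readr::write_csv(env, p2); add(p2)
    env
  })

  # process metrics
  results$metrics <- run_stage("metrics", {
    m <- process_metrics(series)
    p <- file.path(out_dir, "process_metrics.csv")
    readr::write_csv(m, p); add(p)
    m
  })

  # assay summary
  results$assays <- run_stage("assay", {
    blanks <- generate_blanks(config$blank_mean, config$blank_sd,
                              config$blank_n, seed = config$seed)
    bs <- blank_statistics(blanks)
    dl <- detection_limits(bs)
    p <- file.path(out_dir, "detection_limits.yaml")
    .write_yaml_report(list(
      mean_blank = bs$mean_blank, sd_blank = bs$sd_blank,
      n_used = bs$n_used, n_excluded = bs$n_excluded,
      normality_p = bs$normality_p, lod = dl$lod, loq = dl$loq), p)
    add(p)
    list(blank_statistics = bs, detection_limits = dl)
  })

  # productivity vs ComX
  results$q_curve <- run_stage("q_vs_comx", {
    grid <- seq(min(rep1$time_h), max(rep1$time_h), length.out = 201)
    qc <- q_vs_comx(results$fits$biomass, results$fits$surfactin,
                    results$fits$comx, grid)
    p <- file.path(out_dir, "q_vs_comx.csv")
    readr::write_csv(tibble::as_tibble(qc), p); add(p)
    qc
  })

  results$manifest <- finish()
  invisible(results)
}
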