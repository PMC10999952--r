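#' Read a pipeline configuration
#'
#' Configurations are plain YAML.  Top-level keys: `seed`; either
#' `scenario:` (arguments to [sim_scenario()]) or `data:` (a station CSV
#' path, optionally `diet:` a diet CSV path); `covariates:` (a list of
#' `{name, form, transform}` entries, each fitted in its own model);
#' `model:` (mesh and optimizer settings passed to
#' [delta_model_config()]); `n_draws` for the bias correction; `cv_folds`
#' (0 disables cross-validation).
#'
#' @param path YAML file.
#' @return A validated config list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  validate_pipeline_config(yaml::read_yaml(path))
}

#' @rdname read_pipeline_config
#' @param config A config list to validate directly.
#' @export
validate_pipeline_config <- function(config) {
  if (is.null(config$seed)) stop("config must set a seed")
  if (is.null(config$scenario) && is.null(config$data)) {
    stop("config needs either 'scenario' (synthetic) or 'data' (CSV)")
  }
  if (!is.null(config$data) && !file.exists(config$data)) {
    stop("station file not found: ", config$data)
  }
  if (!is.null(config$diet) && is.character(config$diet) &&
      !file.exists(config$diet)) {
    stop("diet file not found: ", config$diet)
  }
  config$n_draws <- config$n_draws %||% 500
  config$cv_folds <- config$cv_folds %||% 3
  config$covariates <- config$covariates %||% list()
  config$model <- config$model %||% list()
  config
}

make_model_config <- function(config, covariate = NULL) {
  args <- config$model
  args$seed <- config$seed
  args$mesh_seed <- args$mesh_seed %||% config$seed
  if (!is.null(covariate)) {
    args$covariate <- covariate$name
    args$form <- covariate$form %||% "linear"
    args$transform <- covariate$transform %||% "identity"
  }
  do.call(delta_model_config, args)
}

write_fit_json <- function(fit, path) {
  sf <- summary(fit$sdreport, select = "fixed")
  jsonlite::write_json(list(
    parameters = data.frame(name = rownames(sf),
                            estimate = unname(sf[, 1]),
                            se = unname(sf[, 2])),
    field_params = unclass(fit$field_params),
    gamma_obs_cv = fit$gamma_obs_cv,
    gamma_raw = as.list(fit$gamma_raw),
    logml = fit$logml,
    max_abs_grad = fit$max_abs_grad,
    converged = fit$converged,
    flagged_years = fit$flagged_years,
    n_records = nrow(fit$data),
    n_knots = nrow(fit$mesh$knots)
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full analysis pipeline
#'
#' Read or simulate the survey -> build the mesh -> fit the base
#' spatio-temporal model -> one fit per configured covariate -> percent
#' deviance explained (both definitions) -> bias-corrected annual indices
#' -> diet summary -> polynomial trend regressions -> diagnostics
#' (Pearson residuals and, when enabled, threefold cross-validation).
#' Every stage writes a CSV or JSON file under `out_dir`; a run log
#' records the package version, config hash, seeds, and per-fit
#' convergence statistics.  A stage failure halts the pipeline with the
#' stage name; outputs of completed stages are retained.
#'
#' @param config A config list ([read_pipeline_config()]) or a YAML path.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the fits, indices, diet and trend
#'   tables, and `all_converged`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(package_version = as.character(utils::packageVersion("sockidx")),
              config_hash = config_hash(config), seed = config$seed,
              started = "run", stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## data
  sim <- NULL
  grid_cov <- NULL
  stations <- stage("data", {
    if (!is.null(config$scenario)) {
      sc <- do.call(sim_scenario,
                    c(config$scenario, list(seed = config$seed)))
      sim <- simulate_survey(sc)
      grid_cov <- sim$grid_covariates
      sim$stations
    } else {
      read_stations(config$data)
    }
  })
  for (cv in config$covariates) {
    if (!cv$name %in% names(stations)) {
      stop("pipeline stage 'validate' failed: covariate '", cv$name,
           "' not present in the station data", call. = FALSE)
    }
    if (anyNA(stations[[cv$name]])) {
      stations <- fill_missing_covariate(stations, cv$name)
    }
  }
  write.csv(stations, file.path(out_dir, "stations.csv"),
            row.names = FALSE)

  ## mesh + base fit
  base_cfg <- make_model_config(config)
  mesh <- stage("mesh", build_mesh(stations, n_knots = base_cfg$n_knots,
                                   buffer_km = base_cfg$buffer_km,
                                   grid_spacing_km = base_cfg$grid_spacing_km,
                                   seed = base_cfg$mesh_seed))
  write_mesh_csv(mesh, file.path(out_dir, "mesh_knots.csv"),
                 file.path(out_dir, "mesh_grid.csv"))
  fit_base <- stage("base_fit", fit_delta_model(stations, base_cfg,
                                                mesh = mesh))
  write_fit_json(fit_base, file.path(out_dir, "fit_base.json"))
  log$stages$base_fit <- list(logml = fit_base$logml,
                              max_abs_grad = fit_base$max_abs_grad,
                              converged = fit_base$converged)

  ## covariate fits + deviance explained + effect curves
  cov_fits <- list()
  dev_rows <- list()
  for (cv in config$covariates) {
    nm <- cv$name
    fit_c <- stage(paste0("fit_", nm), {
      fit_delta_model(stations, make_model_config(config, cv),
                      mesh = mesh)
    })
    cov_fits[[nm]] <- fit_c
    write_fit_json(fit_c, file.path(out_dir,
                                    paste0("fit_", nm, ".json")))
    de <- deviance_explained(fit_base, fit_c)
    dev_rows[[nm]] <- data.frame(covariate = nm,
                                 pct_deviance = de$pct_deviance,
                                 pct_epsilon = de$pct_epsilon)
    ec <- effect_curve(fit_c)
    ec$peak <- attr(ec, "peak")
    write.csv(ec, file.path(out_dir, paste0("effect_", nm, ".csv")),
              row.names = FALSE)
    log$stages[[paste0("fit_", nm)]] <-
      list(logml = fit_c$logml, max_abs_grad = fit_c$max_abs_grad,
           converged = fit_c$converged)
  }
  if (length(dev_rows)) {
    write.csv(do.call(rbind, dev_rows),
              file.path(out_dir, "deviance_explained.csv"),
              row.names = FALSE)
  }

  ## indices with bias correction (from the base model)
  surf <- stage("density_surface", predict_density(fit_base))
  write.csv(surf, file.path(out_dir, "density_surface.csv"),
            row.names = FALSE)
  indices <- stage("indices", {
    bias_correct_indices(fit_base, n_draws = config$n_draws,
                         seed = config$seed + 1)
  })
  write.csv(indices, file.path(out_dir, "indices.csv"),
            row.names = FALSE)

  ## diet
  diet_summary <- NULL
  diet <- stage("diet", {
    if (!is.null(config$diet) && is.character(config$diet)) {
      read.csv(config$diet, stringsAsFactors = FALSE)
    } else if (!is.null(sim)) {
      simulate_diet(sim$truth$scenario)
    } else NULL
  })
  if (!is.null(diet)) {
    write.csv(diet, file.path(out_dir, "diet.csv"), row.names = FALSE)
    diet_summary <- stage("diet_summary", annual_diet_summary(diet))
    write.csv(diet_summary, file.path(out_dir, "diet_summary.csv"),
              row.names = FALSE)
  }

  ## trend regressions: indices vs annual covariate means
  trends <- stage("trends", {
    series <- indices[, c("year", "index", "northing_km", "easting_km",
                          "eao_km2")]
    cov_names <- vapply(config$covariates, `[[`, "", "name")
    cov_names <- unique(c(cov_names,
                          if ("temp20" %in% names(stations)) "temp20"))
    for (nm in cov_names) {
      if (!nm %in% names(stations)) next
      ann <- tapply(stations[[nm]], stations$year, mean)
      series[[nm]] <- as.numeric(ann[match(series$year, names(ann))])
    }
    preds <- setdiff(names(series), c("year", "index", "northing_km",
                                      "easting_km", "eao_km2"))
    if (length(preds) && nrow(series) >= 4) {
      trend_table(series, c("index", "northing_km", "easting_km",
                            "eao_km2"), preds)
    } else NULL
  })
  if (!is.null(trends)) {
    write.csv(trends, file.path(out_dir, "trends.csv"),
              row.names = FALSE)
  }

  ## diagnostics
  res <- stage("residuals", pearson_residuals(fit_base))
  write.csv(cbind(stations[c("station_id", "year")], res),
            file.path(out_dir, "residuals.csv"), row.names = FALSE)
  cv_out <- NULL
  if (config$cv_folds >= 2) {
    cv_out <- stage("cross_validation", {
      cross_validate(stations, base_cfg, n_folds = config$cv_folds,
                     seed = config$seed + 2)
    })
    write.csv(cv_out$folds, file.path(out_dir, "cv_folds.csv"),
              row.names = FALSE)
    write.csv(data.frame(set = c("in_sample", "pooled"),
                         rbind(cv_out$in_sample, cv_out$pooled)),
              file.path(out_dir, "cv_summary.csv"), row.names = FALSE)
  }

  all_converged <- fit_base$converged &&
    all(vapply(cov_fits, `[[`, TRUE, "converged"))
  log$all_converged <- all_converged
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(stations = stations, mesh = mesh, fit_base = fit_base,
                 cov_fits = cov_fits,
                 deviance = if (length(dev_rows))
                   do.call(rbind, dev_rows) else NULL,
                 indices = indices, diet_summary = diet_summary,
                 trends = trends, cv = cv_out,
                 all_converged = all_converged))
}

# stable hash of the configuration (md5 of its deparsed form)
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config[order(names(config))]), f)
  unname(tools::md5sum(f))
}
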