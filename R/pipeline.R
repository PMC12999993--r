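pipeline_config_defaults <- function() {
  list(
    seed = 1L,
    n_per_biome = 182L,          # 11 biomes -> 2,002 observations
    noise_sd = 0.05,
    soc_unit = "g_kg",
    iqr_factor = 1.5,
    iqr_targets = c("nue", "pue"),
    vif_threshold = 5,
    exclude_outliers = FALSE,
    covariates = c("map", "mat", "pet", "humidity", "soc", "ph", "silt",
                   "clay", "cec", "bsat", "depth", "ndvi"),
    responses = c("nue", "pue"),
    cv_n_iter = 100L,
    cv_train_frac = 0.8,
    cv_models = c("mlr", "stepwise", "elastic_net", "lar", "cubist",
                  "bagged_tree", "boosted_tree", "random_forest"),
    rf_n_trees = 500L,
    rf_n_perm = 500L,
    rf_n_null = 0L,
    pdp_points = 100L,
    pdp_predictors = "soc",
    alpha = 0.05,
    grid_n_rows = 60L,
    grid_n_cols = 60L,
    stages = c("simulate", "estimate", "qc", "gapfill", "cv", "fit",
               "importance", "pdp", "map", "summarize")
  )
}

#' Pipeline configuration
#'
#' All stage constants of the analysis pipeline in one validated list:
#' screening constants (IQR factor 1.5, VIF threshold 5), cross-validation
#' settings (100 iterations, 80/20 split), forest settings (500 trees, 500
#' permutations, 100 partial-dependence points), the significance level, the
#' synthetic-data settings and the root seed.  Unknown keys are rejected.
#' Round-trips losslessly through its YAML serialization
#' ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param ... overrides of the defaults (see
#'   `ecostoich:::pipeline_config_defaults`).
#' @return object of class `pipeline_config`.
#' @export
#' @examples
#' cfg <- pipeline_config(seed = 7, cv_n_iter = 10)
pipeline_config <- function(...) {
  cfg <- pipeline_config_defaults()
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) || (length(overrides) && any(names(overrides) == "")))
    stop("unknown pipeline config key(s): ",
         paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  bad_stage <- setdiff(cfg$stages, pipeline_config_defaults()$stages)
  if (length(bad_stage))
    stop("unknown pipeline stage(s): ", paste(bad_stage, collapse = ", "))
  stopifnot(cfg$iqr_factor >= 0, cfg$vif_threshold > 1,
            cfg$cv_train_frac > 0, cfg$cv_train_frac < 1,
            cfg$alpha > 0, cfg$alpha < 1)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

write_stage_csv <- function(df, outdir, name) {
  path <- file.path(outdir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order -- simulate, estimate, qc,
#' gapfill, cv, fit, importance, pdp, map, summarize -- writing every
#' artifact into `outdir` together with a manifest (content hashes of all
#' outputs, the config, seed and package version).  A rerun with the same
#' config and inputs reproduces all seeded outputs byte for byte.  A stage
#' failure halts the run with the stage name after persisting the partial
#' manifest.
#'
#' @param cfg a [pipeline_config()].
#' @param outdir output directory (created).
#' @return invisibly, a list of in-memory stage results; artifacts and
#'   `manifest.json` live in `outdir`.
#' @export
run_pipeline <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  state <- list()
  counts <- list()
  log_stage <- function(stage, n_in, n_out)
    counts[[stage]] <<- list(rows_in = n_in, rows_out = n_out)

  persist_manifest <- function(status) {
    manifest <- list(
      package = "ecostoich",
      version = as.character(utils::packageVersion("ecostoich")),
      r_version = as.character(getRversion()),
      seed = cfg$seed,
      status = status,
      config = unclass(cfg),
      stage_counts = counts,
      files = {
        rel <- sub(paste0(normalizePath(outdir), .Platform$file.sep), "",
                   vapply(files, normalizePath, ""), fixed = TRUE)
        lapply(stats::setNames(files, rel), function(f)
          unname(tools::md5sum(f)))
      }
    )
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  run_stage <- function(stage, fun) {
    if (!stage %in% cfg$stages) return(invisible(NULL))
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      persist_manifest(paste0("failed:", stage))
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(res)), call. = FALSE)
    }
    res
  }

  run_stage("simulate", function() {
    sim <- generate_observations(sim_config(n_per_biome = cfg$n_per_biome,
                                            seed = cfg$seed,
                                            noise_sd = cfg$noise_sd))
    state$sim <<- sim
    files <<- c(files, write_stage_csv(sim$observations, outdir,
                                       "observations.csv"))
    truth_path <- file.path(outdir, "truth.json")
    jsonlite::write_json(sim$truth, truth_path, auto_unbox = TRUE,
                         digits = NA)
    files <<- c(files, truth_path)
    state$grid <<- generate_covariate_grid(sim_config(seed = cfg$seed),
                                           n_rows = cfg$grid_n_rows,
                                           n_cols = cfg$grid_n_cols,
                                           seed = cfg$seed)
    grid_dir <- file.path(outdir, "covariate_grid")
    write_covariate_grid(state$grid, grid_dir)
    files <<- c(files, list.files(grid_dir, full.names = TRUE))
    log_stage("simulate", 0L, nrow(sim$observations))
  })

  run_stage("estimate", function() {
    obs <- state$sim$observations
    comp <- check_completeness(obs)
    est <- estimate_efficiencies(comp$retained, soc_unit = cfg$soc_unit)
    state$est <<- est
    files <<- c(files, write_stage_csv(est, outdir, "estimates.csv"))
    if (nrow(comp$log))
      files <<- c(files, write_stage_csv(comp$log, outdir,
                                         "completeness_log.csv"))
    log_stage("estimate", nrow(obs), nrow(est))
  })

  run_stage("qc", function() {
    est <- state$est
    n_in <- nrow(est)
    reports <- lapply(stats::setNames(cfg$iqr_targets, cfg$iqr_targets),
                      function(v) flag_outliers_iqr(est[[v]],
                                                    cfg$iqr_factor))
    out_tab <- do.call(rbind, lapply(names(reports), function(v) {
      r <- reports[[v]]
      data.frame(variable = v, q1 = r$q1, q3 = r$q3, lower = r$lower,
                 upper = r$upper, n_flagged = r$n_flagged)
    }))
    files <<- c(files, write_stage_csv(out_tab, outdir, "qc_outliers.csv"))
    if (cfg$exclude_outliers) {
      drop <- Reduce(`|`, lapply(reports, `[[`, "flags"))
      est <- est[!drop, , drop = FALSE]
    }
    vif <- screen_vif(est[cfg$covariates], cfg$vif_threshold)
    state$covariates <<- names(vif$retained)
    files <<- c(files, write_stage_csv(
      data.frame(variable = names(vif$retained), vif = unname(vif$retained)),
      outdir, "qc_vif.csv"))
    state$est <<- est
    log_stage("qc", n_in, nrow(est))
  })

  run_stage("gapfill", function() {
    filled <- fill_from_grids(state$est, state$grid,
                              fields = intersect(cfg$covariates,
                                                 names(state$grid$layers)))
    state$est <<- filled
    files <<- c(files, write_stage_csv(filled, outdir, "estimates_filled.csv"))
    log_stage("gapfill", nrow(filled), nrow(filled))
  })

  for (response in cfg$responses) {
    model_data <- function() {
      d <- state$est[c(response, state$covariates)]
      d[stats::complete.cases(d), , drop = FALSE]
    }

    run_stage("cv", function() {
      specs <- default_model_specs(n_trees = cfg$rf_n_trees)[cfg$cv_models]
      cmp <- compare_models(model_data(), response, specs,
                            n_iter = cfg$cv_n_iter,
                            train_frac = cfg$cv_train_frac, seed = cfg$seed)
      state[[paste0("cv_", response)]] <<- cmp
      files <<- c(files, write_stage_csv(cmp$table, outdir,
                                         sprintf("cv_summary_%s.csv",
                                                 response)))
      iters <- do.call(rbind, lapply(cmp$results, function(r)
        data.frame(model = r$model, iteration = seq_along(r$r2),
                   r2 = r$r2, rmse = r$rmse)))
      files <<- c(files, write_stage_csv(iters, outdir,
                                         sprintf("cv_iterations_%s.csv",
                                                 response)))
      log_stage("cv", nrow(model_data()), nrow(cmp$table))
    })

    run_stage("fit", function() {
      model <- fit_rf(model_data(), response, state$covariates,
                      n_trees = cfg$rf_n_trees, seed = cfg$seed)
      state[[paste0("rf_", response)]] <<- model
      files <<- c(files, write_stage_csv(
        data.frame(response = response, n = nrow(model$data),
                   n_trees = model$n_trees, oob_mse = model$oob_mse,
                   var_explained = model$var_explained),
        outdir, sprintf("rf_fit_%s.csv", response)))
      log_stage("fit", nrow(model_data()), nrow(model$data))
    })

    run_stage("importance", function() {
      model <- state[[paste0("rf_", response)]]
      imp <- importance_incmse(model, n_perm = cfg$rf_n_perm,
                               seed = cfg$seed, n_null = cfg$rf_n_null)
      state[[paste0("importance_", response)]] <<- imp
      files <<- c(files, write_stage_csv(as.data.frame(imp), outdir,
                                         sprintf("importance_%s.csv",
                                                 response)))
      log_stage("importance", nrow(model$data), nrow(imp))
    })

    run_stage("pdp", function() {
      model <- state[[paste0("rf_", response)]]
      curves <- do.call(rbind, lapply(cfg$pdp_predictors, function(p) {
        cv <- partial_dependence(model, p, n_grid = cfg$pdp_points)
        data.frame(predictor = p, value = cv$value, yhat = cv$yhat)
      }))
      files <<- c(files, write_stage_csv(curves, outdir,
                                         sprintf("pdp_%s.csv", response)))
      log_stage("pdp", nrow(model$data), nrow(curves))
    })

    run_stage("map", function() {
      model <- state[[paste0("rf_", response)]]
      pg <- predict_grid(model, state$grid)
      state[[paste0("map_", response)]] <<- pg
      map_dir <- file.path(outdir, sprintf("prediction_grid_%s", response))
      write_covariate_grid(pg, map_dir)
      files <<- c(files, list.files(map_dir, full.names = TRUE))
      log_stage("map", prod(grid_dim(state$grid)), prod(grid_dim(pg)))
    })

    run_stage("summarize", function() {
      est <- state$est
      summ <- anova_tukey(est[[response]], est$biome, alpha = cfg$alpha)
      state[[paste0("summary_", response)]] <<- summ
      files <<- c(files, write_stage_csv(as.data.frame(summ), outdir,
                                         sprintf("biome_summary_%s.csv",
                                                 response)))
      log_stage("summarize", nrow(est), nrow(summ))
    })
  }

  persist_manifest("ok")
  invisible(state)
}
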