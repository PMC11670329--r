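#' Pipeline run configuration
#'
#' Nested configuration for the end-to-end synthetic run: simulate ->
#' preprocess -> train (CNN, CNN-LSTM) -> ensemble -> evaluate ->
#' importance -> select. Any subset of stages can be toggled; later stages
#' read the artifacts earlier stages wrote, so a disabled stage's outputs
#' must already exist in `out_dir` for its dependents to run.
#'
#' @param out_dir Directory for all stage artifacts (created if missing).
#' @param sim A [sim_config()] for the data stage.
#' @param split_seed Seed for [split_by_combination()].
#' @param norm_scope `"train"` or `"all"` normalisation fitting support.
#' @param soil If `TRUE`, a synthetic state-level soil table is merged and
#'   the models get a soil branch.
#' @param cnn,cnn_lstm [architecture_spec()]s for the two base models.
#' @param train_cnn,train_cnn_lstm [training_config()]s for the two base
#'   models (distinct seeds recommended).
#' @param importance_reps,importance_seed Permutation-importance settings.
#' @param importance_granularity `"variable"` or `"period"`.
#' @param importance_variable Weather variable for period granularity.
#' @param select_k,select_group_by Genotype-selection settings.
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "preprocess", "train", "ensemble", "evaluate",
#'   "importance", "select")`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       sim = sim_config(),
                       split_seed = 1L,
                       norm_scope = "train",
                       soil = FALSE,
                       cnn = architecture_spec("cnn"),
                       cnn_lstm = architecture_spec("cnn_lstm"),
                       train_cnn = training_config(seed = 11L),
                       train_cnn_lstm = training_config(seed = 12L),
                       importance_reps = 10L,
                       importance_seed = 1L,
                       importance_granularity = "variable",
                       importance_variable = "MDNI",
                       select_k = 10L,
                       select_group_by = "environment",
                       stages = c("simulate", "preprocess", "train",
                                  "ensemble", "evaluate", "importance",
                                  "select")) {
  known <- c("simulate", "preprocess", "train", "ensemble", "evaluate",
             "importance", "select")
  abort_if(!all(stages %in% known),
           "unknown stages: ", paste(setdiff(stages, known), collapse = ", "))
  structure(list(out_dir = out_dir, sim = sim, split_seed = as.integer(split_seed),
                 norm_scope = norm_scope, soil = isTRUE(soil),
                 cnn = cnn, cnn_lstm = cnn_lstm,
                 train_cnn = train_cnn, train_cnn_lstm = train_cnn_lstm,
                 importance_reps = as.integer(importance_reps),
                 importance_seed = as.integer(importance_seed),
                 importance_granularity = importance_granularity,
                 importance_variable = importance_variable,
                 select_k = as.integer(select_k),
                 select_group_by = select_group_by,
                 stages = stages),
            class = "run_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Reads a YAML file whose top-level keys mirror the arguments of
#' [run_config()] (with `sim`, `cnn`, `cnn_lstm`, `train_cnn` and
#' `train_cnn_lstm` given as nested maps of the corresponding constructor
#' arguments) and builds the validated configuration.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw
  if (!is.null(raw$sim)) {
    sim_args <- raw$sim
    if (!is.null(sim_args$effect_sds)) {
      sim_args$effect_sds <- unlist(sim_args$effect_sds)
    }
    args$sim <- do.call(sim_config, sim_args)
  }
  for (f in c("cnn", "cnn_lstm")) {
    if (!is.null(raw[[f]])) {
      spec_args <- raw[[f]]
      spec_args$variant <- f
      args[[f]] <- do.call(architecture_spec, spec_args)
    }
  }
  for (f in c("train_cnn", "train_cnn_lstm")) {
    if (!is.null(raw[[f]])) args[[f]] <- do.call(training_config, raw[[f]])
  }
  do.call(run_config, args)
}

artifact_paths <- function(out_dir) {
  list(data = file.path(out_dir, "data.csv"),
       truth = file.path(out_dir, "truth.json"),
       features = file.path(out_dir, "features.rds"),
       split = file.path(out_dir, "split.csv"),
       cnn = file.path(out_dir, "model_cnn.rds"),
       cnn_lstm = file.path(out_dir, "model_cnn_lstm.rds"),
       weights = file.path(out_dir, "weights.json"),
       report = file.path(out_dir, "report.json"),
       importance = file.path(out_dir, "importance.csv"),
       selection = file.path(out_dir, "selection.csv"),
       manifest = file.path(out_dir, "manifest.json"))
}

#' Run the end-to-end pipeline
#'
#' Executes the enabled stages in dependency order, writing each stage's
#' artifact under `config$out_dir` and a manifest (inputs, outputs, seeds,
#' wall times) at the end. Stages whose outputs already exist are skipped
#' unless `force = TRUE`; a stage whose upstream artifact is missing fails
#' with an error naming the stage to run.
#'
#' @param config A [run_config()] or path to a YAML file for
#'   [read_run_config()].
#' @param force Re-run stages whose outputs already exist.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, force = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  abort_if(!inherits(config, "run_config"), "config must be a run_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- artifact_paths(config$out_dir)
  manifest <- list(stages = list(),
                   seeds = list(data = config$sim$seed,
                                split = config$split_seed,
                                train_cnn = config$train_cnn$seed,
                                train_cnn_lstm = config$train_cnn_lstm$seed,
                                importance = config$importance_seed))
  enabled <- function(s) s %in% config$stages
  fresh <- function(ps) force || !all(file.exists(unlist(ps)))
  need <- function(path, stage) {
    abort_if(!file.exists(path),
             "missing upstream artifact ", basename(path),
             "; run stage '", stage, "' first")
  }
  timed <- function(name, outputs, expr) {
    t0 <- Sys.time()
    ran <- FALSE
    if (fresh(outputs)) {
      expr()
      ran <- TRUE
    }
    manifest$stages[[name]] <<- list(
      ran = ran, outputs = unname(unlist(outputs)),
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }

  if (enabled("simulate")) {
    timed("simulate", paths[c("data", "truth")], function() {
      sim <- simulate_dataset(config$sim)
      write_trial_csv(sim$records, paths$data)
      write_truth_json(sim$truth, paths$truth)
    })
  }

  if (enabled("preprocess")) {
    timed("preprocess", paths[c("features", "split")], function() {
      need(paths$data, "simulate")
      records <- read_trial_csv(paths$data)
      if (config$soil) {
        records <- merge_soil(records,
                              synthetic_soil_table(records$state,
                                                   seed = config$sim$seed))
      }
      split <- split_by_combination(records, seed = config$split_seed)
      registry <- build_category_registry(records[split$train, , drop = FALSE])
      feats <- build_features(records, registry, split = split,
                              norm_scope = config$norm_scope)
      saveRDS(list(features = feats, split = split), paths$features)
      write_split_csv(split, paths$split)
    })
  }

  load_features <- function(stage) {
    need(paths$features, "preprocess")
    readRDS(paths$features)
  }

  if (enabled("train")) {
    timed("train", paths[c("cnn", "cnn_lstm")], function() {
      fs <- load_features("train")
      n_soil <- if (is.null(fs$features$soil)) NULL else ncol(fs$features$soil)
      for (v in c("cnn", "cnn_lstm")) {
        spec <- config[[v]]
        if (config$soil && is.null(spec$soil_branch)) {
          spec$soil_branch <- list(units = 512L, dropout = 0.5)
        }
        tc <- config[[paste0("train_", v)]]
        model <- build_model(spec, n_other = ncol(fs$features$onehot),
                             n_soil = n_soil, seed = tc$seed)
        model <- train_network(model, fs$features, fs$split$train, tc)
        saveRDS(model, paths[[v]])
      }
    })
  }

  base_predictions <- function(models, fs, mask) {
    vapply(models, function(m) predict(m, fs$features, rows = mask),
           numeric(sum(mask)))
  }

  if (enabled("ensemble")) {
    timed("ensemble", paths["weights"], function() {
      fs <- load_features("ensemble")
      need(paths$cnn, "train")
      models <- list(cnn = readRDS(paths$cnn))
      if (file.exists(paths$cnn_lstm)) {
        models$cnn_lstm <- readRDS(paths$cnn_lstm)
      }
      preds <- base_predictions(models, fs, fs$split$validation)
      colnames(preds) <- names(models)
      w <- fit_gem(preds, fs$features$y[fs$split$validation])
      jsonlite::write_json(list(model_ids = w$model_ids,
                                weights = unname(w$weights),
                                val_mse = w$objective),
                           paths$weights, auto_unbox = TRUE, digits = NA)
    })
  }

  read_ensemble <- function() {
    need(paths$weights, "ensemble")
    wj <- jsonlite::read_json(paths$weights, simplifyVector = TRUE)
    models <- lapply(setNames(wj$model_ids, wj$model_ids), function(id) {
      need(paths[[id]], "train")
      readRDS(paths[[id]])
    })
    w <- structure(list(weights = setNames(wj$weights, wj$model_ids),
                        objective = wj$val_mse, model_ids = wj$model_ids),
                   class = "gem_weights")
    gem_ensemble(models, w)
  }

  if (enabled("evaluate")) {
    timed("evaluate", paths["report"], function() {
      fs <- load_features("evaluate")
      ens <- read_ensemble()
      report <- list()
      for (split_name in c("train", "validation", "test")) {
        mask <- fs$split[[split_name]]
        y <- fs$features$y[mask]
        preds <- lapply(ens$models, function(m)
          predict(m, fs$features, rows = mask))
        preds$gem <- gem_predict(ens$weights,
                                 do.call(cbind, unname(preds)))
        report[[split_name]] <- lapply(preds, function(p) {
          r <- evaluation_report(y, p, split_name)
          list(rmse = r$rmse, mae = r$mae, r = r$r, n = r$n)
        })
      }
      jsonlite::write_json(report, paths$report, auto_unbox = TRUE,
                           digits = NA)
    })
  }

  if (enabled("importance")) {
    timed("importance", paths["importance"], function() {
      fs <- load_features("importance")
      ens <- read_ensemble()
      test_feats <- subset_features(fs$features, fs$split$test)
      groups <- define_groups(test_feats,
                              granularity = config$importance_granularity,
                              variable = config$importance_variable)
      imp <- rmse_change(ens, test_feats, groups,
                         repetitions = config$importance_reps,
                         seed = config$importance_seed)
      data.table::fwrite(imp, paths$importance)
    })
  }

  if (enabled("select")) {
    timed("select", paths["selection"], function() {
      need(paths$data, "simulate")
      records <- read_trial_csv(paths$data)
      if (config$soil) {
        records <- merge_soil(records,
                              synthetic_soil_table(records$state,
                                                   seed = config$sim$seed))
      }
      ens <- read_ensemble()
      sel <- selection_gap_report(ens, records, k = config$select_k,
                                  group_by = config$select_group_by)
      data.table::fwrite(sel, paths$selection)
    })
  }

  manifest$out_dir <- config$out_dir
  manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
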