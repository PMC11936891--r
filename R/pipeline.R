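#' Default pipeline run configuration
#'
#' A nested list understood by [run_pipeline()] and the stage runner
#' [pipeline_stage()]. The defaults describe a small, fast synthetic run;
#' set the `paths` entries to use pre-existing rasters, clips or tables
#' instead of simulating.
#'
#' @param seed global seed propagated to every stochastic stage.
#' @return Named list of stage settings.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    synthetic = list(n_families = 6L, n_progeny_per_family = 8L,
                     n_replications = 3L),
    paths = list(orthoimage = NULL, truth = NULL, layout = NULL),
    top_fraction = 0.10,
    split = list(test_frac = 0.10, n_folds = 3L, val_frac = 0.20,
                 stratify_on = "score_class"),
    rf = list(n_trees = 200L, grid_search = FALSE, criterion = NULL,
              max_depth = NULL, ccp_alpha = 0, class_weight = "none"),
    cnn = list(enabled = FALSE, epochs = 15L, batch_size = 32L,
               learning_rate = 1e-3, input_size = 32L),
    tasks = c("dmy", "top", "score"),
    models = c("benchmark", "rf"))
}

#' Read a pipeline configuration from YAML
#'
#' Settings present in the file override the defaults of
#' [default_run_config()]; unknown keys are rejected.
#'
#' @param path YAML file.
#' @param seed optional seed overriding the file's.
#' @return Configuration list.
#' @export
read_run_config <- function(path, seed = NULL) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (k in names(user)) {
    cfg[[k]] <- if (is.list(cfg[[k]]) && is.list(user[[k]]))
      utils::modifyList(cfg[[k]], user[[k]]) else user[[k]]
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

write_manifest <- function(out_dir, stage, inputs, outputs, seed) {
  existing <- inputs[file.exists(inputs)]
  man <- list(stage = stage,
              inputs = as.list(tools::md5sum(existing)),
              outputs = as.list(tools::md5sum(outputs[file.exists(outputs)])),
              seed = seed,
              package_version = as.character(utils::packageVersion("rgbpheno")))
  jsonlite::write_json(man, file.path(out_dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE)
  invisible(man)
}

pipeline_paths <- function(out_dir) {
  list(orthoimage = file.path(out_dir, "orthoimage.png"),
       truth = file.path(out_dir, "truth.csv"),
       layout = file.path(out_dir, "layout.yml"),
       clips = file.path(out_dir, "clips"),
       features = file.path(out_dir, "features.csv"),
       split = file.path(out_dir, "split.json"),
       benchmark = file.path(out_dir, "benchmark.json"),
       report = file.path(out_dir, "report.json"),
       report_csv = file.path(out_dir, "report.csv"))
}

require_artifacts <- function(paths, stage) {
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("stage '", stage, "' is missing upstream artifact(s): ",
         paste(missing, collapse = ", "))
}

#' Run one pipeline stage
#'
#' Stages read their inputs from, and write their outputs and a checksum
#' manifest to, `out_dir`; upstream artifacts are never modified. Available
#' stages: `simulate`, `clip`, `extract`, `split`, `train-benchmark`,
#' `train-rf`, `train-cnn`, `evaluate`, `report`. `evaluate` covers the
#' models listed in `config$models`; `report` assembles one summary row
#' per model and task.
#'
#' @param stage stage name.
#' @param config configuration list ([default_run_config()]).
#' @param out_dir run directory, created if absent.
#' @return Invisibly, the stage's main artifact path.
#' @export
pipeline_stage <- function(stage, config = default_run_config(), out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p <- pipeline_paths(out_dir)
  seed <- as.integer(config$seed)
  switch(stage,
    "simulate" = {
      args <- config$synthetic
      args$rng_seed <- seed
      field <- generate_field(do.call(field_config, args))
      write_orthoimage(field$orthoimage, p$orthoimage)
      write_truth_table(field, p$truth)
      write_layout(field$layout, p$layout)
      write_manifest(out_dir, stage, character(0),
                     c(p$orthoimage, p$truth, p$layout), seed)
      invisible(p$truth)
    },
    "clip" = {
      require_artifacts(c(p$orthoimage, p$layout), stage)
      ortho <- read_orthoimage(p$orthoimage)
      layout <- read_layout(p$layout)
      plots <- clip_plots(ortho, layout, source = p$orthoimage)
      write_clips(plots, p$clips)
      write_manifest(out_dir, stage, c(p$orthoimage, p$layout),
                     file.path(p$clips, paste0(vapply(plots, function(x) x$plot_id, ""), ".png")),
                     seed)
      invisible(p$clips)
    },
    "extract" = {
      require_artifacts(p$clips, stage)
      plots <- read_clips(p$clips)
      X <- extract_feature_matrix(plots)
      write_feature_matrix(X, p$features)
      write_manifest(out_dir, stage,
                     list.files(p$clips, full.names = TRUE), p$features, seed)
      invisible(p$features)
    },
    "split" = {
      require_artifacts(p$truth, stage)
      records <- read_plot_table(p$truth)
      sp <- config$split
      split <- make_splits(records, test_frac = sp$test_frac,
                           n_folds = sp$n_folds, val_frac = sp$val_frac,
                           stratify_on = sp$stratify_on, rng_seed = seed)
      write_split(split, p$split)
      write_manifest(out_dir, stage, p$truth, p$split, seed)
      invisible(p$split)
    },
    "train-benchmark" = {
      require_artifacts(c(p$truth, p$split), stage)
      records <- read_plot_table(p$truth)
      split <- read_split(p$split)
      train <- records[!(records$plot_id %in% split$test_ids), ]
      bm <- fit_benchmark(train)
      jsonlite::write_json(list(score_means = as.list(bm$score_means),
                                fallback_mean = bm$fallback_mean, n = bm$n),
                           p$benchmark, auto_unbox = TRUE, digits = NA)
      write_manifest(out_dir, stage, c(p$truth, p$split), p$benchmark, seed)
      invisible(p$benchmark)
    },
    "train-rf" = ,
    "train-cnn" = ,
    "evaluate" = {
      require_artifacts(c(p$truth, p$split, p$features), stage)
      res <- evaluate_run(config, out_dir)
      out <- vapply(names(res), function(nm)
        file.path(out_dir, paste0("eval_", nm, ".json")), "")
      for (nm in names(res)) write_eval_report(res[[nm]], out[[nm]])
      write_manifest(out_dir, stage, c(p$truth, p$split, p$features),
                     out, seed)
      invisible(out)
    },
    "report" = {
      evals <- list.files(out_dir, pattern = "^eval_.*\\.json$",
                          full.names = TRUE)
      if (!length(evals)) stop("stage 'report' found no evaluation artifacts")
      rows <- lapply(evals, function(f) {
        e <- jsonlite::read_json(f, simplifyVector = TRUE)
        parts <- strsplit(sub("^eval_", "", sub("\\.json$", "", basename(f))),
                          "_")[[1]]
        data.frame(model = parts[1], task = parts[2],
                   r2 = e$r2 %||% NA_real_, rmse_g = e$rmse_g %||% NA_real_,
                   balanced_accuracy = e$balanced_accuracy %||% NA_real_,
                   f1_macro = e$f1_macro %||% NA_real_,
                   f2_select = e$f2_select %||% NA_real_)
      })
      report <- do.call(rbind, rows)
      report <- report[order(report$model, report$task), ]
      rownames(report) <- NULL
      utils::write.csv(report, p$report_csv, row.names = FALSE, quote = FALSE)
      jsonlite::write_json(report, p$report, auto_unbox = TRUE, digits = NA)
      write_manifest(out_dir, stage, evals, c(p$report, p$report_csv), seed)
      invisible(p$report)
    },
    stop("unknown stage: ", stage))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

task_response <- function(records, task, top_fraction = 0.10) {
  switch(task,
    dmy = records$dmy_g,
    top = top_performer_labels(records$dmy_g, top_fraction),
    score = as.character(aggregate_scores(records$breeder_score)),
    stop("unknown task: ", task))
}

task_model_kind <- function(task) {
  switch(task, dmy = "regression", top = "top_binary",
         score = "score_3class")
}

# Fit the configured models on the non-test records and evaluate them on
# the test partition. Returns a named list of eval_reports keyed
# "<model>_<task>".
evaluate_run <- function(config, out_dir) {
  p <- pipeline_paths(out_dir)
  records <- read_plot_table(p$truth)
  split <- read_split(p$split)
  X <- read_feature_matrix(p$features)
  X <- X[records$plot_id, , drop = FALSE]
  is_test <- records$plot_id %in% split$test_ids
  train_rec <- records[!is_test, ]
  seed <- as.integer(config$seed)

  reports <- list()
  for (task in config$tasks) {
    y_all <- task_response(records, task, config$top_fraction)
    kind <- task_model_kind(task)
    y_test <- y_all[is_test]

    if ("benchmark" %in% config$models && task == "dmy") {
      bm <- fit_benchmark(train_rec)
      pred <- predict(bm, records$breeder_score[is_test])
      reports[["benchmark_dmy"]] <- evaluate_predictions(y_test, pred, kind)
    }
    if ("rf" %in% config$models) {
      rfc <- config$rf
      eng_kind <- if (kind == "regression") "regression" else "classification"
      if (isTRUE(rfc$grid_search)) {
        gs <- grid_search_rf(X, y_all, task = kind,
                             grid = rf_grid(eng_kind, n_trees = rfc$n_trees,
                                            rng_seed = seed),
                             split = split)
        bc <- gs$best_config
        rfc$criterion <- bc$criterion; rfc$max_depth <- bc$max_depth
        rfc$ccp_alpha <- bc$ccp_alpha; rfc$class_weight <- bc$class_weight
        write_grid_search(gs, file.path(out_dir, paste0("cv_", task, ".csv")),
                          file.path(out_dir, paste0("best_", task, ".json")))
      }
      cw <- if (eng_kind == "regression") "none"
            else rfc$class_weight %||% "none"
      fit <- rf_fit(X[!is_test, , drop = FALSE], y_all[!is_test],
                    task = eng_kind, n_trees = rfc$n_trees,
                    criterion = rfc$criterion, max_depth = rfc$max_depth,
                    ccp_alpha = rfc$ccp_alpha %||% 0, class_weight = cw,
                    rng_seed = seed + 17L)
      pred <- predict(fit, X[is_test, , drop = FALSE])
      if (eng_kind == "classification") pred <- as.character(pred)
      reports[[paste0("rf_", task)]] <-
        evaluate_predictions(y_test, pred, kind,
                             class_order = fit$class_levels)
      imp <- compute_importance(fit)
      utils::write.csv(imp, file.path(out_dir, paste0("importance_", task, ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
    if ("cnn" %in% config$models && isTRUE(config$cnn$enabled)) {
      plots <- read_clips(p$clips)
      ids <- vapply(plots, function(x) x$plot_id, "")
      ord <- match(records$plot_id, ids)
      plots <- plots[ord]
      cc <- cnn_config(
        head_outputs = switch(kind, regression = 1L, top_binary = 2L,
                              score_3class = 3L),
        epochs = config$cnn$epochs, batch_size = config$cnn$batch_size,
        learning_rate = config$cnn$learning_rate,
        input_size = config$cnn$input_size, rng_seed = seed + 29L)
      fold <- split$folds[[1]]
      cnn <- train_cnn(plots, y_all, cc, fold)
      pred <- predict(cnn, plots[is_test])
      reports[[paste0("cnn_", task)]] <-
        evaluate_predictions(y_test, pred, kind,
                             class_order = cnn$class_levels)
    }
  }
  reports
}

#' Run the full pipeline end to end
#'
#' Executes `simulate`, `clip`, `extract`, `split`, `train-benchmark`,
#' `evaluate` and `report` in order (simulation is skipped when the
#' configuration points at existing artifacts). A rerun with the same
#' configuration and seed produces an identical report.
#'
#' @param config a configuration list ([default_run_config()]) or the path
#'   of a YAML file for [read_run_config()].
#' @param out_dir run directory.
#' @return The report data frame, invisibly.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stages <- c("simulate", "clip", "extract", "split", "train-benchmark",
              "evaluate", "report")
  if (!is.null(config$paths$orthoimage)) stages <- setdiff(stages, "simulate")
  for (s in stages) pipeline_stage(s, config, out_dir)
  invisible(utils::read.csv(pipeline_paths(out_dir)$report_csv))
}
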