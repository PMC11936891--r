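#' Hyperparameter grid of the random-forest models
#'
#' The fixed settings are 1000 trees and the standard per-tree feature
#' count (square root of the feature total for classification, one third
#' for regression). Four hyperparameters are searched: balanced class
#' weights yes/no (classification only), the split criterion (Gini
#' impurity / entropy for classification; squared error / Friedman /
#' absolute error / Poisson deviance for regression), the maximum tree
#' depth (3 / 5 / 7) and the cost-complexity pruning strength (ten evenly
#' spaced values from 0.001 to 1; `log_spaced_alpha = TRUE` switches to
#' log spacing over the same range). Either grid has 120 cells:
#' 2 x 2 x 3 x 10 for classification, 4 x 3 x 10 for regression.
#'
#' @param task `"classification"` or `"regression"`.
#' @param n_trees trees per forest; 1000 is the study setting, smaller
#'   values keep exploratory searches fast.
#' @param log_spaced_alpha use log-spaced pruning values.
#' @param rng_seed integer seed for the fits.
#' @return An object of class `rf_grid`: a list with the axis values and a
#'   `cells` data frame enumerating the full grid.
#' @export
rf_grid <- function(task = c("classification", "regression"),
                    n_trees = 1000L, log_spaced_alpha = FALSE,
                    rng_seed = 1L) {
  task <- match.arg(task)
  alphas <- if (log_spaced_alpha)
    exp(seq(log(0.001), log(1), length.out = 10L))
  else seq(0.001, 1, length.out = 10L)
  criteria <- if (task == "classification") c("gini", "entropy")
              else c("mse", "friedman_mse", "mae", "poisson")
  class_weights <- if (task == "classification") c("balanced", "none")
                   else "none"
  cells <- expand.grid(class_weight = class_weights, criterion = criteria,
                       max_depth = c(3L, 5L, 7L), ccp_alpha = alphas,
                       stringsAsFactors = FALSE)
  structure(list(task = task, n_trees = as.integer(n_trees),
                 criteria = criteria, class_weights = class_weights,
                 max_depths = c(3L, 5L, 7L), ccp_alphas = alphas,
                 cells = cells, rng_seed = as.integer(rng_seed)),
            class = "rf_grid")
}

#' @export
print.rf_grid <- function(x, ...) {
  cat(sprintf("<rf_grid (%s): %d cells x (%d trees each)>\n",
              x$task, nrow(x$cells), x$n_trees))
  invisible(x)
}

task_kind <- function(task) {
  switch(task, regression = "regression",
         top_binary = , score_3class = "classification",
         stop("unknown task: ", task))
}

#' Cross-validated grid search for the random-forest models
#'
#' Evaluates every grid cell on all train/validation folds of `split`. The
#' selection metric is the mean validation R-squared (regression) or mean
#' validation balanced accuracy (classification) across folds; ties are
#' broken towards the simpler model (smaller maximum depth, then stronger
#' pruning, then the listed criterion and class-weight order). The full
#' per-cell, per-fold table is returned for audit.
#'
#' @param x feature matrix with plot ids as rownames.
#' @param y responses aligned with the rows of `x`.
#' @param task `"regression"`, `"top_binary"` or `"score_3class"`.
#' @param grid an [rf_grid()]; defaults to the task's standard grid.
#' @param split a [make_splits()] result whose ids index rows of `x`.
#' @return An object of class `rf_grid_search`: list with `best_config`
#'   (one-row data frame), `cv_table` (one row per cell x fold) and
#'   `metric` (name of the selection metric).
#' @export
grid_search_rf <- function(x, y, task = c("regression", "top_binary",
                                          "score_3class"),
                           grid = NULL, split) {
  task <- match.arg(task)
  kind <- task_kind(task)
  if (is.null(grid)) grid <- rf_grid(kind)
  if (grid$task != kind)
    stop("grid task '", grid$task, "' does not match model task '", task, "'")
  if (nrow(grid$cells) == 0L) stop("empty grid")
  ids <- rownames(x)
  if (is.null(ids)) stop("feature matrix must have plot ids as rownames")
  if (length(y) != nrow(x)) stop("features and labels are misaligned")
  if (kind == "classification") y <- as.character(y)

  metric_name <- if (kind == "regression") "val_r2" else "val_balanced_accuracy"
  cells <- grid$cells
  rows <- vector("list", nrow(cells) * length(split$folds))
  ri <- 0L
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    for (fi in seq_along(split$folds)) {
      fold <- split$folds[[fi]]
      tr <- match(fold$train_ids, ids); va <- match(fold$val_ids, ids)
      if (anyNA(tr) || anyNA(va))
        stop("split ids not found among feature matrix rownames")
      fit <- rf_fit(x[tr, , drop = FALSE], y[tr], task = kind,
                    n_trees = grid$n_trees, criterion = cell$criterion,
                    max_depth = cell$max_depth, ccp_alpha = cell$ccp_alpha,
                    class_weight = cell$class_weight,
                    rng_seed = grid$rng_seed + 131L * ci)
      pred <- predict(fit, x[va, , drop = FALSE])
      m <- if (kind == "regression") r2(y[va], pred)
           else ba_present(y[va], as.character(pred), fit$class_levels)
      ri <- ri + 1L
      rows[[ri]] <- cbind(cell, fold = fi, metric = m, row.names = NULL)
    }
  }
  cv_table <- do.call(rbind, rows)
  names(cv_table)[names(cv_table) == "metric"] <- metric_name

  agg <- stats::aggregate(
    cv_table[[metric_name]],
    by = cv_table[c("class_weight", "criterion", "max_depth", "ccp_alpha")],
    FUN = mean)
  names(agg)[ncol(agg)] <- "mean_metric"
  ord <- order(-agg$mean_metric, agg$max_depth, -agg$ccp_alpha,
               match(agg$criterion, grid$criteria),
               match(agg$class_weight, grid$class_weights))
  best <- agg[ord[1], , drop = FALSE]
  rownames(best) <- NULL
  structure(list(best_config = best, cv_table = cv_table,
                 metric = metric_name, task = task, grid = grid),
            class = "rf_grid_search")
}

#' @export
print.rf_grid_search <- function(x, ...) {
  cat(sprintf("<rf_grid_search (%s): %d cells x %d folds; best mean %s = %.3f>\n",
              x$task, nrow(x$grid$cells),
              nrow(x$cv_table) / nrow(x$grid$cells), x$metric,
              x$best_config$mean_metric))
  print.data.frame(x$best_config)
  invisible(x)
}

#' Write grid-search results
#'
#' The cv table goes to CSV and the best configuration to JSON.
#'
#' @param gs an [grid_search_rf()] result.
#' @param cv_path,best_path output paths.
#' @export
write_grid_search <- function(gs, cv_path, best_path) {
  utils::write.csv(gs$cv_table, cv_path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(as.list(gs$best_config), best_path,
                       auto_unbox = TRUE, digits = NA)
  invisible(gs)
}
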