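#' Node impurity / splitting criteria
#'
#' Reference implementations of the split criteria used by the forest,
#' evaluated on the contents of a single node. For classification,
#' `entropy` is \eqn{-\sum_i p_i \ln p_i} over the class proportions
#' (natural logarithm) and `gini` is \eqn{1 - \sum_i p_i^2}. For
#' regression, `mse` is the mean squared deviation from the node mean,
#' `mae` the mean absolute deviation from the node median, and `poisson`
#' the mean Poisson deviance around the node mean. These closed forms
#' serve as an independent oracle for verifying the tree engine's split
#' semantics on depth-1 stumps.
#'
#' @param values_or_labels node contents: class labels (classification
#'   criteria) or numeric responses (regression criteria).
#' @param criterion one of `"entropy"`, `"gini"`, `"mse"`, `"mae"`,
#'   `"poisson"`.
#' @return The criterion value, a single non-negative number.
#' @export
node_criterion <- function(values_or_labels,
                           criterion = c("entropy", "gini", "mse", "mae",
                                         "poisson")) {
  criterion <- match.arg(criterion)
  x <- values_or_labels
  if (length(x) == 0L) stop("empty node")
  switch(criterion,
    entropy = {
      p <- as.vector(table(x)) / length(x)
      p <- p[p > 0]
      -sum(p * log(p))
    },
    gini = {
      p <- as.vector(table(x)) / length(x)
      1 - sum(p^2)
    },
    mse = mean((x - mean(x))^2),
    mae = mean(abs(x - stats::median(x))),
    poisson = {
      if (any(x < 0)) stop("poisson deviance requires non-negative values")
      mu <- mean(x)
      if (mu == 0) return(0)
      term <- ifelse(x > 0, x * log(x / mu), 0)
      mean(2 * (term - (x - mu)))
    })
}

# ---- rpart user-written split methods ------------------------------------

# Sum of absolute deviations from the median for every prefix of y.
# O(n^2) memory/time; intended for the moderate node sizes of this package.
prefix_absdev <- function(y) {
  n <- length(y)
  if (n == 0L) return(numeric(0))
  med <- vapply(seq_len(n), function(j) stats::median(y[seq_len(j)]), 0)
  A <- abs(outer(y, med, "-"))
  colSums(A * upper.tri(A, diag = TRUE))
}

# Friedman's improvement criterion for regression splits:
# w_l w_r / (w_l + w_r) * (mean_l - mean_r)^2.
method_friedman_mse <- function() {
  list(
    init = function(y, offset, parms = NULL, wt) {
      list(y = y, parms = parms, numresp = 1L, numy = 1L,
           summary = function(yval, dev, wt, ylevel, digits)
             paste("  mean =", format(signif(yval, digits))))
    },
    eval = function(y, wt, parms) {
      wmean <- sum(y * wt) / sum(wt)
      list(label = wmean, deviance = sum(wt * (y - wmean)^2))
    },
    split = function(y, wt, x, parms, continuous) {
      if (!continuous) stop("friedman_mse splitting supports continuous features only")
      n <- length(y)
      wl <- cumsum(wt)[-n]; wr <- sum(wt) - wl
      sl <- cumsum(wt * y)[-n]; sr <- sum(wt * y) - sl
      good <- wl * wr / (wl + wr) * (sl / wl - sr / wr)^2
      list(goodness = good, direction = rep(-1, n - 1L))
    })
}

# Mean-absolute-error (median) regression splits. Unit weights only.
method_mae <- function() {
  list(
    init = function(y, offset, parms = NULL, wt) {
      if (length(unique(wt)) > 1L)
        stop("mae splitting supports unit weights only")
      list(y = y, parms = parms, numresp = 1L, numy = 1L,
           summary = function(yval, dev, wt, ylevel, digits)
             paste("  median =", format(signif(yval, digits))))
    },
    eval = function(y, wt, parms) {
      m <- stats::median(y)
      list(label = m, deviance = sum(abs(y - m)))
    },
    split = function(y, wt, x, parms, continuous) {
      if (!continuous) stop("mae splitting supports continuous features only")
      n <- length(y)
      if (n > 5000L) stop("mae splitting supports nodes up to 5000 observations")
      parent <- sum(abs(y - stats::median(y)))
      left <- prefix_absdev(y)[-n]
      right <- rev(prefix_absdev(rev(y)))[-1]
      good <- pmax(0, parent - (left + right))
      list(goodness = good, direction = rep(-1, n - 1L))
    })
}

rpart_method_for <- function(criterion, task) {
  if (task == "classification") {
    switch(criterion,
      gini = list(method = "class", parms = list(split = "gini")),
      entropy = list(method = "class", parms = list(split = "information")),
      stop("unknown classification criterion: ", criterion))
  } else {
    switch(criterion,
      mse = list(method = "anova", parms = NULL),
      poisson = list(method = "poisson", parms = NULL),
      friedman_mse = list(method = method_friedman_mse(), parms = NULL),
      mae = list(method = method_mae(), parms = NULL),
      stop("unknown regression criterion: ", criterion))
  }
}

# ---- the forest ----------------------------------------------------------

#' Fit a random forest of bagged CART trees
#'
#' An ensemble of `n_trees` CART trees, each grown by \pkg{rpart} on a
#' bootstrap sample of the observations using a random subspace of `mtry`
#' features. The engine exposes the full criterion set (Gini impurity and
#' entropy for classification; squared error, Friedman's improvement,
#' absolute error and Poisson deviance for regression), a maximum tree
#' depth, cost-complexity pruning and balanced class weights.
#'
#' `ccp_alpha` is the cost-complexity pruning strength expressed per
#' observation: each tree is pruned at the equivalent \pkg{rpart}
#' complexity parameter `cp = ccp_alpha * n / deviance(root)`, so
#' `ccp_alpha = 0` leaves trees unpruned and values near 1 collapse them
#' to the root. With `class_weight = "balanced"`, each observation of class
#' j receives weight `N / (C * n_j)` so every class contributes equally to
#' the splitting criterion.
#'
#' @param x numeric feature matrix (rows = observations, named columns).
#' @param y response: numeric (regression) or factor/character
#'   (classification).
#' @param task `"regression"` or `"classification"` (inferred from `y`
#'   when omitted).
#' @param n_trees number of trees (the pipeline default is 1000).
#' @param criterion split criterion; defaults to `"gini"` / `"mse"`.
#' @param max_depth maximum tree depth, or `NULL` for unlimited (engine
#'   cap 30).
#' @param ccp_alpha cost-complexity pruning strength, >= 0.
#' @param class_weight `"none"` or `"balanced"` (classification only).
#' @param mtry features drawn per tree; defaults to `sqrt(p)` for
#'   classification and `p/3` for regression.
#' @param min_split minimum node size to attempt a split.
#' @param rng_seed integer seed; fits are bit-for-bit reproducible.
#' @return An object of class `rf_ensemble`.
#' @export
rf_fit <- function(x, y, task = NULL, n_trees = 1000L, criterion = NULL,
                   max_depth = NULL, ccp_alpha = 0,
                   class_weight = c("none", "balanced"), mtry = NULL,
                   min_split = 2L, rng_seed = 1L) {
  class_weight <- match.arg(class_weight)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- nrow(x); p <- ncol(x)
  stopifnot(length(y) == n, n >= 2L, n_trees >= 1L)
  if (is.null(task))
    task <- if (is.numeric(y)) "regression" else "classification"
  task <- match.arg(task, c("regression", "classification"))
  if (is.null(criterion))
    criterion <- if (task == "classification") "gini" else "mse"
  if (task == "classification") {
    y <- factor(y, levels = if (is.factor(y)) levels(y) else unique(y))
    class_levels <- levels(y)
  } else {
    y <- as.numeric(y)
    class_levels <- NULL
    if (class_weight == "balanced")
      stop("balanced class weights apply to classification only")
    if (criterion == "poisson" && any(y < 0))
      stop("poisson criterion requires non-negative responses")
  }
  if (is.null(mtry))
    mtry <- if (task == "classification") max(1L, floor(sqrt(p)))
            else max(1L, floor(p / 3))
  mtry <- min(as.integer(mtry), p)

  wts <- rep(1, n)
  if (class_weight == "balanced") {
    tab <- table(y)
    wts <- as.numeric(n / (length(tab) * tab[as.character(y)]))
  }

  meth <- rpart_method_for(criterion, task)
  ctrl <- rpart::rpart.control(
    minsplit = min_split, minbucket = 1L, cp = 0, xval = 0L,
    maxcompete = 0L, maxsurrogate = 0L, usesurrogate = 0L,
    maxdepth = if (is.null(max_depth)) 30L else as.integer(max_depth))

  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(rng_seed)

  trees <- vector("list", n_trees)
  for (b in seq_len(n_trees)) {
    boot <- sample.int(n, n, replace = TRUE)
    feats <- sort(sample.int(p, mtry))
    df <- data.frame(.y = y[boot], x[boot, feats, drop = FALSE],
                     check.names = FALSE)
    fit_args <- list(.y ~ ., data = df, weights = wts[boot],
                     method = meth$method, control = ctrl)
    if (!is.null(meth$parms)) fit_args$parms <- meth$parms
    fit <- do.call(rpart::rpart, fit_args)
    if (ccp_alpha > 0) {
      root_dev <- fit$frame$dev[1]
      if (root_dev > 0) {
        cp_equiv <- min(1, ccp_alpha * sum(wts[boot]) / root_dev)
        fit <- rpart::prune(fit, cp = cp_equiv)
      }
    }
    trees[[b]] <- list(fit = fit, features = colnames(x)[feats])
  }
  structure(list(trees = trees, task = task, criterion = criterion,
                 n_trees = n_trees, mtry = mtry, max_depth = max_depth,
                 ccp_alpha = ccp_alpha, class_weight = class_weight,
                 class_levels = class_levels, feature_names = colnames(x),
                 schema_version = attr(x, "schema_version"),
                 rng_seed = as.integer(rng_seed)),
            class = "rf_ensemble")
}

#' @export
print.rf_ensemble <- function(x, ...) {
  cat(sprintf("<rf_ensemble: %d %s trees, criterion %s, mtry %d, depth %s, ccp_alpha %g, class_weight %s>\n",
              x$n_trees, x$task, x$criterion, x$mtry,
              if (is.null(x$max_depth)) "unlimited" else x$max_depth,
              x$ccp_alpha, x$class_weight))
  invisible(x)
}

check_feature_schema <- function(object, newx) {
  if (is.null(colnames(newx)))
    stop("new data must carry feature names matching the fitted model")
  if (!identical(colnames(newx), object$feature_names))
    stop("feature schema mismatch: new data columns do not match the ",
         "model's feature manifest")
}

#' Predict from a bagged CART forest
#'
#' Regression forests average the tree predictions; classification forests
#' take the majority vote (ties broken by class order). `type = "prob"`
#' returns the vote fractions per class.
#'
#' @param object an [rf_fit()] model.
#' @param newx feature matrix with the same named columns as at fit time.
#' @param type `"response"` or `"prob"` (classification only).
#' @param ... unused.
#' @export
predict.rf_ensemble <- function(object, newx,
                                type = c("response", "prob"), ...) {
  type <- match.arg(type)
  newx <- as.matrix(newx)
  check_feature_schema(object, newx)
  nd <- as.data.frame(newx, check.names = FALSE)
  if (object$task == "regression") {
    preds <- vapply(object$trees, function(tr)
      as.numeric(predict(tr$fit, nd[, tr$features, drop = FALSE])),
      numeric(nrow(nd)))
    if (nrow(nd) == 1L) preds <- matrix(preds, nrow = 1L)
    return(rowMeans(preds))
  }
  lv <- object$class_levels
  votes <- matrix(0, nrow(nd), length(lv), dimnames = list(NULL, lv))
  for (tr in object$trees) {
    cl <- as.character(predict(tr$fit, nd[, tr$features, drop = FALSE],
                               type = "class"))
    votes[cbind(seq_len(nrow(nd)), match(cl, lv))] <-
      votes[cbind(seq_len(nrow(nd)), match(cl, lv))] + 1
  }
  if (type == "prob") return(votes / object$n_trees)
  factor(lv[max.col(votes, ties.method = "first")], levels = lv)
}

#' Mean-decrease-in-impurity feature importance
#'
#' For every feature, sums the split-criterion reduction achieved by the
#' primary splits on that feature across all trees of the forest, and
#' normalises so the importances sum to 1 (Gini importance / MDI). Features
#' never used receive importance 0.
#'
#' @param forest an [rf_fit()] model.
#' @return An object of class `importance_table`: data frame with columns
#'   `feature` and `importance`, sorted decreasing.
#' @export
compute_importance <- function(forest) {
  if (!inherits(forest, "rf_ensemble")) stop("not a fitted rf_ensemble")
  imp <- setNames(numeric(length(forest$feature_names)),
                  forest$feature_names)
  for (tr in forest$trees) {
    sp <- tr$fit$splits
    if (is.null(sp) || nrow(sp) == 0L) next
    gain <- sp[, "improve"]
    # rpart stores anova improvements relative to the splitting node's own
    # deviance; rescale to absolute criterion reductions so a root split
    # outweighs a deep one. Classification, poisson and the user-written
    # criteria already store absolute reductions.
    if (forest$criterion == "mse") {
      node_dev <- tr$fit$frame$dev[tr$fit$frame$var != "<leaf>"]
      gain <- gain * node_dev
    }
    gains <- tapply(gain, rownames(sp), sum)
    imp[names(gains)] <- imp[names(gains)] + gains
  }
  total <- sum(imp)
  if (total <= 0) {
    warning("forest contains no splits; importances are all zero")
  } else imp <- imp / total
  out <- data.frame(feature = names(imp), importance = unname(imp),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$feature), ]
  rownames(out) <- NULL
  structure(out, class = c("importance_table", "data.frame"))
}

#' @export
print.importance_table <- function(x, n = 10L, ...) {
  cat(sprintf("<importance_table: %d features; top %d>\n", nrow(x), n))
  print.data.frame(head(x, n), digits = 4)
  invisible(x)
}

#' Threshold-based feature selection from MDI importances
#'
#' `mean_threshold` keeps features whose importance is at least the mean of
#' all importances (1/p when importances sum to 1); `absolute_0.01` keeps
#' features with at least 1\% of the combined importance. The top-ranked
#' feature is always retained so the selection is never empty.
#'
#' @param importance an [compute_importance()] table.
#' @param mode `"mean_threshold"` or `"absolute_0.01"`.
#' @return Character vector of retained feature names.
#' @export
select_features <- function(importance,
                            mode = c("mean_threshold", "absolute_0.01")) {
  mode <- match.arg(mode)
  if (nrow(importance) == 0L) stop("empty importance table")
  thr <- if (mode == "mean_threshold") mean(importance$importance) else 0.01
  keep <- importance$feature[importance$importance >= thr]
  if (length(keep) == 0L)
    keep <- importance$feature[which.max(importance$importance)]
  keep
}
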