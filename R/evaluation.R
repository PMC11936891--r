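#' Coefficient of determination and root mean square error
#'
#' `r2` is `1 - SSE/SST` (can be negative for a predictor worse than the
#' mean); `rmse` is `sqrt(mean((observed - predicted)^2))`, in the units of
#' the response (grams for yield).
#'
#' @param observed,predicted equal-length numeric vectors.
#' @return A single number.
#' @export
r2 <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) > 0)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("R-squared is undefined: observed values have zero variance")
  1 - sum((observed - predicted)^2) / sst
}

#' @rdname r2
#' @export
rmse <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) > 0)
  sqrt(mean((observed - predicted)^2))
}

#' Confusion matrix
#'
#' Counts of (true class, predicted class) pairs; rows are true classes,
#' columns predicted classes, in the order given by `class_order`.
#'
#' @param true_labels,predicted_labels vectors of labels drawn from
#'   `class_order`.
#' @param class_order character vector fixing row/column order.
#' @return An object of class `confusion_matrix`: integer matrix with
#'   dimnames `true` x `predicted`.
#' @export
confusion <- function(true_labels, predicted_labels, class_order) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  unknown <- setdiff(unique(c(true_labels, predicted_labels)), class_order)
  if (length(unknown))
    stop("label(s) not in class_order: ", paste(unknown, collapse = ", "))
  tf <- factor(true_labels, levels = class_order)
  pf <- factor(predicted_labels, levels = class_order)
  m <- table(true = tf, predicted = pf)
  structure(unclass(m), class = "confusion_matrix")
}

#' Row-normalise a confusion matrix
#'
#' Each row is divided by its sum (per-true-class rates); rows with zero
#' sum are reported as zeros.
#'
#' @param cm a [confusion()] matrix.
#' @return Numeric matrix of the same shape.
#' @export
normalise_confusion <- function(cm) {
  rs <- rowSums(cm)
  out <- sweep(unclass(cm), 1, ifelse(rs == 0, 1, rs), "/")
  out[rs == 0, ] <- 0
  out
}

# One-vs-rest TP/FP/FN/TN for one class. Internal.
ovr_counts <- function(cm, positive_class) {
  cm <- unclass(cm)
  i <- match(positive_class, rownames(cm))
  if (is.na(i)) stop("unknown class: ", positive_class)
  tp <- cm[i, i]
  fn <- sum(cm[i, ]) - tp
  fp <- sum(cm[, i]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Precision, recall and specificity for one class
#'
#' One-vs-rest rates: precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`. A zero denominator yields 0, flagged in the
#' `degenerate` attribute.
#'
#' @param cm a [confusion()] matrix.
#' @param positive_class class treated as positive.
#' @return Named numeric vector `(precision, recall, specificity)`.
#' @export
prs <- function(cm, positive_class) {
  k <- ovr_counts(cm, positive_class)
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  out <- c(precision = safe_div(k["tp"], k["tp"] + k["fp"]),
           recall = safe_div(k["tp"], k["tp"] + k["fn"]),
           specificity = safe_div(k["tn"], k["tn"] + k["fp"]))
  names(out) <- c("precision", "recall", "specificity")
  attr(out, "degenerate") <- c(precision = k[["tp"]] + k[["fp"]] == 0,
                               recall = k[["tp"]] + k[["fn"]] == 0,
                               specificity = k[["tn"]] + k[["fp"]] == 0)
  out
}

#' Balanced accuracy
#'
#' The unweighted mean of per-class recalls, insensitive to class
#' prevalence. Every true class must be present (a class with no true
#' members has no recall).
#'
#' @param cm a [confusion()] matrix.
#' @return A single number in `[0, 1]`.
#' @export
balanced_accuracy <- function(cm) {
  rs <- rowSums(cm)
  if (any(rs == 0))
    stop("true class(es) absent from evaluation set: ",
         paste(rownames(cm)[rs == 0], collapse = ", "))
  mean(diag(unclass(cm)) / rs)
}

#' F-beta measure
#'
#' `(1 + beta^2) * P * R / (beta^2 * P + R)`, and 0 when both precision and
#' recall are 0. `beta = 1` weighs them equally; `beta = 2` favours recall,
#' appropriate when losing a strong selection candidate costs more than
#' retaining a weak one.
#'
#' @param precision,recall rates in `[0, 1]`.
#' @param beta positive weight on recall.
#' @return A single number in `[0, 1]`.
#' @export
f_beta <- function(precision, recall, beta = 1) {
  stopifnot(beta > 0, precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision == 0 && recall == 0) return(0)
  (1 + beta^2) * precision * recall / (beta^2 * precision + recall)
}

#' Evaluate predictions with the task-appropriate metric set
#'
#' Regression (`task = "regression"`) reports R-squared and RMSE.
#' Classification reports the raw and row-normalised confusion matrix,
#' per-class precision/recall/specificity and balanced accuracy, plus the
#' F2-measure for the Select class (`task = "top_binary"`) or the
#' macro-averaged F1 over the three classes (`task = "score_3class"`).
#'
#' @param observed true responses (numeric for regression, labels
#'   otherwise).
#' @param predicted model predictions, same type as `observed`.
#' @param task one of `"regression"`, `"top_binary"`, `"score_3class"`.
#' @param class_order label order; defaults to `c("Select", "Discard")` or
#'   `c("1", "2", "3")` by task.
#' @return An object of class `eval_report`.
#' @export
evaluate_predictions <- function(observed, predicted,
                                 task = c("regression", "top_binary",
                                          "score_3class"),
                                 class_order = NULL) {
  task <- match.arg(task)
  if (task == "regression") {
    rep <- list(task = task, n = length(observed),
                r2 = r2(observed, predicted),
                rmse_g = rmse(observed, predicted))
    return(structure(rep, class = "eval_report"))
  }
  if (is.null(class_order))
    class_order <- if (task == "top_binary") c("Select", "Discard")
                   else c("1", "2", "3")
  cm <- confusion(observed, predicted, class_order)
  per_class <- t(vapply(class_order, function(cl) prs(cm, cl), numeric(3)))
  ba <- if (all(rowSums(cm) > 0)) balanced_accuracy(cm) else {
    warning("class(es) absent from the evaluation set; balanced accuracy ",
            "averages the recalls of the classes present")
    ba_present(observed, predicted, class_order)
  }
  rep <- list(task = task, n = sum(cm), confusion = cm,
              confusion_normalised = normalise_confusion(cm),
              per_class = per_class, balanced_accuracy = ba)
  if (task == "top_binary") {
    p <- prs(cm, "Select")
    rep$f2_select <- f_beta(p[["precision"]], p[["recall"]], beta = 2)
  } else {
    f1s <- vapply(class_order, function(cl) {
      p <- prs(cm, cl)
      f_beta(p[["precision"]], p[["recall"]], beta = 1)
    }, 0)
    rep$f1_macro <- mean(f1s)
    rep$f1_per_class <- f1s
  }
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 3, ...) {
  cat(sprintf("<eval_report: %s, n = %d>\n", x$task, x$n))
  if (x$task == "regression") {
    cat(sprintf("  R2 = %.*f, RMSE = %.*f g\n", digits, x$r2, digits, x$rmse_g))
  } else {
    cat(sprintf("  balanced accuracy = %.*f\n", digits, x$balanced_accuracy))
    if (!is.null(x$f2_select))
      cat(sprintf("  F2 (Select) = %.*f\n", digits, x$f2_select))
    if (!is.null(x$f1_macro))
      cat(sprintf("  F1 (macro) = %.*f\n", digits, x$f1_macro))
    cat("  confusion (rows = true):\n")
    print(unclass(x$confusion))
  }
  invisible(x)
}

#' Write an evaluation report to JSON (and the confusion matrix to CSV)
#'
#' @param report an [evaluate_predictions()] result.
#' @param path JSON output path; for classification tasks the normalised
#'   confusion matrix is also written to `<path>.confusion.csv`.
#' @export
write_eval_report <- function(report, path) {
  out <- unclass(report)
  if (!is.null(out$confusion)) {
    out$confusion <- as.data.frame(unclass(out$confusion))
    out$confusion_normalised <- as.data.frame(out$confusion_normalised)
    out$per_class <- as.data.frame(out$per_class)
    utils::write.csv(
      data.frame(true_class = rownames(report$confusion_normalised),
                 report$confusion_normalised, check.names = FALSE),
      paste0(path, ".confusion.csv"), row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
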