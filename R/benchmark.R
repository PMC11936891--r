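#' Fit the breeder's-score benchmark yield model
#'
#' A linear model using the 0-5 breeder's score as a categorical predictor
#' of dry matter yield: with indicator coding of the six score levels, the
#' coefficient for score s is the training-set mean yield of score-s plants,
#' so prediction returns that group mean. The model quantifies the
#' predictive power of the breeder's visual assessment and is the baseline
#' every image-based yield model is compared against.
#'
#' @param records data frame with `dmy_g` and `breeder_score` columns.
#' @return An object of class `benchmark_model` with components
#'   `score_means` (named numeric, one per observed score level) and
#'   `fallback_mean` (global training mean, used for score levels unseen in
#'   training, with a warning).
#' @export
fit_benchmark <- function(records) {
  if (is.null(records) || nrow(records) == 0L) stop("empty training set")
  s <- as.integer(records$breeder_score)
  if (anyNA(s) || any(s < 0L) || any(s > 5L))
    stop("breeder scores must be integers in 0-5")
  means <- tapply(records$dmy_g, factor(s, levels = 0:5), mean)
  means <- setNames(as.numeric(means), names(means))
  structure(list(score_means = means[!is.na(means)],
                 fallback_mean = mean(records$dmy_g),
                 n = nrow(records)),
            class = "benchmark_model")
}

#' @export
print.benchmark_model <- function(x, ...) {
  cat(sprintf("<benchmark_model fitted on %d plots>\n", x$n))
  cat("  mean yield (g) per score level:\n")
  print(round(x$score_means, 2))
  invisible(x)
}

#' @export
coef.benchmark_model <- function(object, ...) object$score_means

#' Predict yield from breeder's scores
#'
#' @param object a [fit_benchmark()] model.
#' @param newdata integer vector of scores 0-5 (or a data frame with a
#'   `breeder_score` column).
#' @param ... unused.
#' @return Numeric vector of predicted yields (grams). Scores unseen in
#'   training receive the global training mean, with a warning.
#' @export
predict.benchmark_model <- function(object, newdata, ...) {
  s <- if (is.data.frame(newdata)) newdata$breeder_score else newdata
  s <- as.character(as.integer(s))
  pred <- unname(object$score_means[s])
  if (anyNA(pred)) {
    warning("score level(s) unseen in training predicted with the global mean: ",
            paste(unique(s[is.na(pred)]), collapse = ", "))
    pred[is.na(pred)] <- object$fallback_mean
  }
  pred
}
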