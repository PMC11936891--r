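#' Aggregate breeder's scores into three classes
#'
#' Scores 4 and 5 form class 1 (good plants), score 3 forms class 2
#' (mediocre), and scores 0-2 form class 3 (poor). The mapping simplifies
#' practical use of model output: good / medium / bad is easier to act on
#' than six levels.
#'
#' @param breeder_score integer vector of scores in 0-5.
#' @return Integer vector of classes in 1-3.
#' @export
aggregate_scores <- function(breeder_score) {
  s <- as.integer(breeder_score)
  if (anyNA(s) || any(s < 0L) || any(s > 5L))
    stop("breeder scores must be integers in 0-5")
  ifelse(s >= 4L, 1L, ifelse(s == 3L, 2L, 3L))
}

#' Label the top-yielding fraction of plants
#'
#' Assigns `"Select"` to exactly `ceiling(fraction * N)` plants with the
#' highest yields and `"Discard"` to the rest. Ties at the selection
#' threshold are broken by ascending position in the input (stable), so the
#' label set is deterministic.
#'
#' @param dmy numeric vector of yields (grams).
#' @param fraction selected fraction, strictly between 0 and 1.
#' @return Character vector of `"Select"` / `"Discard"` labels.
#' @export
top_performer_labels <- function(dmy, fraction = 0.10) {
  n <- length(dmy)
  if (n == 0L) stop("empty yield vector")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  k <- ceiling(fraction * n)
  # order by decreasing yield, ties by ascending input position
  ord <- order(-dmy, seq_len(n))
  labels <- rep("Discard", n)
  labels[ord[seq_len(k)]] <- "Select"
  labels
}

#' Attach derived response variables to a phenotype table
#'
#' Adds `score_class` ([aggregate_scores()]) and `top_label`
#' ([top_performer_labels()]) columns. Relabelling is idempotent.
#'
#' @param records data frame with `dmy_g` and `breeder_score` columns.
#' @param top_fraction fraction used for the top-performers label.
#' @return The records with `score_class` and `top_label` columns.
#' @export
add_response_labels <- function(records, top_fraction = 0.10) {
  records$score_class <- aggregate_scores(records$breeder_score)
  records$top_label <- top_performer_labels(records$dmy_g, top_fraction)
  records
}

# Stratum assignment used for splitting. Internal.
stratum_of <- function(records, stratify_on) {
  switch(stratify_on,
    score_class = as.character(aggregate_scores(records$breeder_score)),
    top_label = top_performer_labels(records$dmy_g),
    dmy_quartile = {
      q <- quantile(records$dmy_g, c(0.25, 0.5, 0.75))
      as.character(findInterval(records$dmy_g, q) + 1L)
    },
    stop("unknown stratification: ", stratify_on))
}

# Sample round(frac * n) ids per stratum. Internal.
stratified_sample <- function(ids, strata, frac) {
  unlist(lapply(split(ids, strata), function(s) {
    k <- round(frac * length(s))
    if (k == 0L) character(0) else sample(s, k)
  }), use.names = FALSE)
}

#' Build a stratified test set and three train/validation splits
#'
#' Reserves a stratified `test_frac` (default 10\%) of the records as a
#' test set, then draws `n_folds` (default 3) independent stratified
#' train/validation splits over the remaining records, each holding out
#' `val_frac` (default 20\%) for validation. Per-stratum proportions in
#' every partition are within one record of the global proportion. The
#' result is deterministic for a fixed seed. By default the three splits
#' are drawn independently; `shared_fold_seed = TRUE` derives all fold
#' seeds from the global seed alone (both interpretations of "three
#' splits" are supported).
#'
#' @param records phenotype data frame with `plot_id`, `dmy_g`,
#'   `breeder_score`.
#' @param test_frac fraction reserved for the test set.
#' @param n_folds number of train/validation splits.
#' @param val_frac validation fraction of the non-test records.
#' @param stratify_on one of `"score_class"`, `"top_label"`,
#'   `"dmy_quartile"` (quartile bins make continuous yield stratifiable).
#' @param rng_seed integer seed.
#' @param shared_fold_seed reuse one seed stream for all folds instead of
#'   per-fold derived seeds (membership still differs between folds).
#' @return An object of class `dataset_split`: list with `test_ids`,
#'   `folds` (each a list with `train_ids`, `val_ids`), `stratify_on`,
#'   `rng_seed`.
#' @export
make_splits <- function(records, test_frac = 0.10, n_folds = 3L,
                        val_frac = 0.20, stratify_on = "score_class",
                        rng_seed = 1L, shared_fold_seed = FALSE) {
  ids <- as.character(records$plot_id)
  if (anyDuplicated(ids)) stop("duplicate plot ids")
  strata <- stratum_of(records, stratify_on)
  sizes <- table(strata)
  small <- names(sizes)[sizes < n_folds]
  if (length(small))
    stop("stratum too small for splitting: ",
         paste(sprintf("'%s' (n=%d)", small, sizes[small]), collapse = ", "))

  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  set.seed(rng_seed)
  test_ids <- stratified_sample(ids, strata, test_frac)
  rest <- !(ids %in% test_ids)
  rest_ids <- ids[rest]; rest_strata <- strata[rest]

  folds <- lapply(seq_len(n_folds), function(f) {
    if (!shared_fold_seed) set.seed(rng_seed + 100003L * f)
    val <- stratified_sample(rest_ids, rest_strata, val_frac)
    list(train_ids = setdiff(rest_ids, val), val_ids = val)
  })
  structure(list(test_ids = test_ids, folds = folds,
                 stratify_on = stratify_on, rng_seed = as.integer(rng_seed)),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split: %d test ids, %d folds (train %d / val %d), stratified on %s, seed %d>\n",
              length(x$test_ids), length(x$folds),
              length(x$folds[[1]]$train_ids), length(x$folds[[1]]$val_ids),
              x$stratify_on, x$rng_seed))
  invisible(x)
}

#' Serialise a dataset split to JSON
#'
#' Written as `{test: [...], folds: [{train: [...], val: [...]}, ...]}`.
#'
#' @param split a [make_splits()] result.
#' @param path JSON output path.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(
    list(test = split$test_ids,
         folds = lapply(split$folds, function(f)
           list(train = f$train_ids, val = f$val_ids)),
         stratify_on = split$stratify_on, rng_seed = split$rng_seed),
    path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    test_ids = as.character(j$test),
    folds = lapply(seq_len(nrow(j$folds)), function(i)
      list(train_ids = as.character(j$folds$train[[i]]),
           val_ids = as.character(j$folds$val[[i]]))),
    stratify_on = as.character(j$stratify_on)[1],
    rng_seed = as.integer(j$rng_seed)[1]),
    class = "dataset_split")
}
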