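# Train/test partitioning and classification metrics, shared by all three
# decision systems.

#' Chronological train/test split at the round boundary
#'
#' The data span two competition rounds; the first round is the training
#' partition and the second the test partition, so no within-player
#' temporal information leaks across the split.
#'
#' @param rows Feature table with a `round` column (from
#'   [aggregate_microcycle()]); if absent, `mc_Microcycle` is compared to
#'   `boundary` directly.
#' @param boundary Round marker: the first round belonging to the test
#'   partition (default 2).
#' @return List with `train` and `test` data frames.
#' @export
split_train_test <- function(rows, boundary = 2L) {
  key <- if ("round" %in% names(rows)) rows$round else rows$mc_Microcycle
  train <- rows[key < boundary, , drop = FALSE]
  test <- rows[key >= boundary, , drop = FALSE]
  if (nrow(train) == 0L || nrow(test) == 0L)
    stop("split error: boundary ", boundary,
         " leaves an empty partition (train ", nrow(train), ", test ",
         nrow(test), ")")
  list(train = train, test = test)
}

#' Confusion matrix and classification metrics for the injury class
#'
#' Positive class is injury (1). When a metric's denominator is zero the
#' metric is reported as `NA` (undefined), not 0; F1 is 0 only when there
#' are no true positives but the denominators are defined.
#'
#' @param labels Binary vector of true labels.
#' @param predictions Binary vector of predicted labels, same length.
#' @return An `eval_report` list: `tp`, `fp`, `fn`, `tn`, `accuracy`,
#'   `precision`, `recall`, `f1`.
#' @export
compute_metrics <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop("input error: labels and predictions differ in length")
  ok <- !is.na(labels) & !is.na(predictions)
  labels <- as.integer(labels[ok]); predictions <- as.integer(predictions[ok])
  if (!all(labels %in% 0:1) || !all(predictions %in% 0:1))
    stop("input error: labels and predictions must be binary")
  tp <- sum(labels == 1L & predictions == 1L)
  fp <- sum(labels == 0L & predictions == 1L)
  fn <- sum(labels == 1L & predictions == 0L)
  tn <- sum(labels == 0L & predictions == 0L)
  n <- tp + fp + fn + tn
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (is.na(precision) || is.na(recall)) NA_real_
  else if (precision + recall > 0) 2 * precision * recall /
    (precision + recall) else 0
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 accuracy = if (n > 0) (tp + tn) / n else NA_real_,
                 precision = precision, recall = recall, f1 = f1),
            class = "eval_report")
}

#' Side-by-side comparison of decision systems on one test set
#'
#' @param labels Binary vector of true labels.
#' @param predictions Named list of binary prediction vectors, one per
#'   model.
#' @return Data frame with one row per model and the metric columns of
#'   [compute_metrics()].
#' @export
compare_models <- function(labels, predictions) {
  rows <- lapply(names(predictions), function(nm) {
    m <- compute_metrics(labels, predictions[[nm]])
    data.frame(model = nm, tp = m$tp, fp = m$fp, fn = m$fn, tn = m$tn,
               accuracy = m$accuracy, precision = m$precision,
               recall = m$recall, f1 = m$f1, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
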