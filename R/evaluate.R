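#' Pixel-wise confusion counts between predicted and true masks
#'
#' TP: MP pixel predicted MP; FP: background predicted MP; TN: background
#' predicted background; FN: MP predicted background.
#'
#' @param pred,truth Binary masks of identical shape.
#' @return Named list (tp, fp, tn, fn); counts sum to the pixel total.
#' @export
confusion <- function(pred, truth) {
  p <- as_mask_matrix(pred); t <- as_mask_matrix(truth)
  if (!all(dim(p) == dim(t))) {
    stopf("mask shapes differ: %s vs %s",
          paste(dim(p), collapse = "x"), paste(dim(t), collapse = "x"))
  }
  tp <- sum(p == 1L & t == 1L)
  fp <- sum(p == 1L & t == 0L)
  fn <- sum(p == 0L & t == 1L)
  tn <- sum(p == 0L & t == 0L)
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

safe_ratio <- function(num, den) if (den > 0) num / den else 0

#' Segmentation metrics from confusion counts
#'
#' Balanced accuracy, recall, precision, F1-score and IoU. Ratios with a
#' zero denominator are reported as 0 and flagged in the `undefined` field
#' so that across-image means stay defined.
#'
#' @param c Confusion counts from [confusion()].
#' @return One-row data.frame: balanced_accuracy, recall, precision, f1,
#'   iou, undefined (comma-separated names of zero-denominator metrics, or
#'   "").
#' @export
seg_metrics <- function(c) {
  undef <- character(0)
  if (c$tp + c$fn == 0) undef <- c(undef, "recall")
  if (c$tp + c$fp == 0) undef <- c(undef, "precision")
  recall <- safe_ratio(c$tp, c$tp + c$fn)
  precision <- safe_ratio(c$tp, c$tp + c$fp)
  if (precision + recall == 0) undef <- union(undef, "f1")
  f1 <- safe_ratio(2 * precision * recall, precision + recall)
  if (c$tp + c$fp + c$fn == 0) undef <- union(undef, "iou")
  iou <- safe_ratio(c$tp, c$tp + c$fp + c$fn)
  specificity <- safe_ratio(c$tn, c$tn + c$fp)
  if (c$tn + c$fp == 0) undef <- c(undef, "balanced_accuracy")
  data.frame(balanced_accuracy = (recall + specificity) / 2,
             recall = recall, precision = precision, f1 = f1, iou = iou,
             undefined = paste(undef, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Average per-image metric rows
#'
#' Unweighted arithmetic mean of each metric column. With a `fold` grouping,
#' per-fold means are computed first and the grand mean is the mean of the
#' fold means (the cross-validated reporting convention; it differs from the
#' pooled mean when folds have unequal sizes).
#'
#' @param reports data.frame of per-image rows from [seg_metrics()].
#' @param folds Optional per-row fold labels.
#' @return List with `mean` (one-row data.frame) and, when `folds` given,
#'   `fold_means` (one row per fold).
#' @export
mean_metrics <- function(reports, folds = NULL) {
  if (nrow(reports) < 1L) stopf("no metric rows to average")
  cols <- c("balanced_accuracy", "recall", "precision", "f1", "iou")
  if (is.null(folds)) {
    return(list(mean = as.data.frame(as.list(colMeans(reports[cols])))))
  }
  stopifnot(length(folds) == nrow(reports))
  fm <- do.call(rbind, lapply(split(reports[cols], folds), colMeans))
  fold_means <- data.frame(fold = rownames(fm), fm, row.names = NULL,
                           stringsAsFactors = FALSE)
  list(mean = as.data.frame(as.list(colMeans(fm))), fold_means = fold_means)
}

#' Pixel-wise majority vote over annotator masks
#'
#' A pixel is foreground iff strictly more than half of the masks mark it
#' foreground; with an even number of masks, ties go to background. Used to
#' fuse independent annotators into a single ground truth.
#'
#' @param masks List of >= 2 binary masks of identical shape (an odd count
#'   avoids ties).
#' @return An [mp_mask()].
#' @export
majority_vote <- function(masks) {
  stopifnot(is.list(masks), length(masks) >= 2L)
  ms <- lapply(masks, as_mask_matrix)
  d <- dim(ms[[1]])
  if (!all(vapply(ms, function(m) all(dim(m) == d), TRUE))) {
    stopf("all masks must share the same shape")
  }
  votes <- Reduce(`+`, ms)
  mp_mask((votes > length(ms) / 2) * 1L)
}

#' Percentage recovery of an MP count
#'
#' `100 * predicted / ground_truth`, rounded half away from zero to an
#' integer percentage. 100 is perfect recovery; values above 100 indicate
#' overestimation.
#'
#' @param predicted Predicted MP count.
#' @param ground_truth True MP count (>= 1).
#' @return Integer percentage.
#' @examples
#' recovery(175, 170) # 103
#' @export
recovery <- function(predicted, ground_truth) {
  stopifnot(is_count(predicted), is_count(ground_truth))
  if (ground_truth < 1) stopf("undefined recovery: ground truth count is 0")
  as.integer(round_half_up(100 * predicted / ground_truth))
}

#' Recovery report over a set of samples
#'
#' Per-sample integer percentage recoveries plus their mean and sample
#' standard deviation (n - 1 denominator), each rounded to one decimal.
#'
#' @param ground_truth,predicted Equal-length integer count vectors.
#' @param ids Optional sample identifiers.
#' @return A `recovery_report`: list with `samples` (data.frame: id,
#'   ground_truth, predicted, recovery_pct), `mean_pct` and `sd_pct`
#'   (1-decimal; `sd_pct` is NA for a single sample).
#' @export
recovery_report <- function(ground_truth, predicted, ids = NULL) {
  n <- length(ground_truth)
  if (n < 1L || length(predicted) != n) {
    stopf("need equal-length, non-empty count vectors")
  }
  if (is.null(ids)) ids <- as.character(seq_len(n))
  rec <- vapply(seq_len(n), function(i) recovery(predicted[i], ground_truth[i]),
                integer(1))
  structure(list(
    samples = data.frame(id = ids, ground_truth = ground_truth,
                         predicted = predicted, recovery_pct = rec,
                         stringsAsFactors = FALSE),
    mean_pct = round(mean(rec), 1),
    sd_pct = if (n >= 2L) round(stats::sd(rec), 1) else NA_real_
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d samples, mean %.1f%% (SD %.1f%%)\n",
              nrow(x$samples), x$mean_pct, x$sd_pct))
  invisible(x)
}

#' Tally under-, exact and over-estimation of MP counts
#'
#' @inheritParams recovery_report
#' @return Named integer vector (under, exact, over) summing to the number
#'   of samples.
#' @export
estimation_tally <- function(ground_truth, predicted) {
  n <- length(ground_truth)
  if (n < 1L || length(predicted) != n) {
    stopf("need equal-length, non-empty count vectors")
  }
  c(under = sum(predicted < ground_truth),
    exact = sum(predicted == ground_truth),
    over = sum(predicted > ground_truth))
}

#' Benchmark MP counts for recovery assessment
#'
#' Ground-truth and per-method predicted MP counts for two published
#' benchmark sets distributed with the package: five spiked images of
#' milled HDPE/PET standards and fifteen images of MP extracted from clams,
#' as reported in a comparative assessment of automated MP quantification
#' tools. Methods: mp_vat, mp_vat2, c_vat, mp_net.
#'
#' @param set `"spiked"` or `"clam"`.
#' @return data.frame: sample, ground_truth, then one predicted-count column
#'   per method.
#' @export
benchmark_counts <- function(set = c("spiked", "clam")) {
  set <- match.arg(set)
  path <- system.file("extdata", paste0(set, "_mp_counts.csv"),
                      package = "mpquant", mustWork = TRUE)
  utils::read.csv(path)
}
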