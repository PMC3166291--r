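check_truth <- function(truth) {
  if (is.character(truth) || is.factor(truth)) {
    truth <- as.character(truth) == "ts"
  }
  if (is.numeric(truth)) truth <- truth > 0
  as.logical(truth)
}

#' Precision on the ts class
#'
#' TP / (TP + FP), where a sample is predicted ts when its confidence
#' exceeds the threshold. Returns `NA` (with a warning) when nothing is
#' predicted ts.
#'
#' @param truth Truth labels: logical, 0/1, or `"ts"`/`"non-ts"`.
#' @param confidence Predicted ts confidences.
#' @param threshold Decision threshold; default 0.5.
#' @return A fraction in \[0, 1\], or `NA` when no positive predictions.
#' @export
ts_precision <- function(truth, confidence, threshold = 0.5) {
  truth <- check_truth(truth)
  pred <- confidence > threshold
  if (!any(pred)) {
    warn("no positive predictions; precision undefined")
    return(NA_real_)
  }
  sum(truth & pred) / sum(pred)
}

#' Confusion counts at a threshold
#'
#' @inheritParams ts_precision
#' @return One-row tibble with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(truth, confidence, threshold = 0.5) {
  truth <- check_truth(truth)
  pred <- confidence > threshold
  tibble::tibble(tp = sum(truth & pred), fp = sum(!truth & pred),
                 tn = sum(!truth & !pred), fn = sum(truth & !pred))
}

check_two_class <- function(truth, what) {
  if (length(unique(truth)) < 2) {
    abort(paste0(what, " is undefined for a single-class truth vector"),
          class = "tsmut_metric_error")
  }
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney rank statistic with half credit
#' for ties: the probability that a randomly chosen ts sample receives a
#' higher confidence than a randomly chosen non-ts sample.
#'
#' @inheritParams ts_precision
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(truth, confidence) {
  truth <- check_truth(truth)
  check_two_class(truth, "AUROC")
  r <- rank(confidence, ties.method = "average")
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' @inheritParams ts_precision
#' @return Tibble of `(fpr, tpr)` points from (0, 0) to (1, 1), one step per
#'   distinct confidence threshold.
#' @export
roc_points <- function(truth, confidence) {
  truth <- check_truth(truth)
  check_two_class(truth, "ROC")
  ord <- order(-confidence)
  truth <- truth[ord]
  conf <- confidence[ord]
  keep <- c(conf[-1] != conf[-length(conf)], TRUE)  # last point of tie blocks
  tibble::tibble(
    fpr = c(0, cumsum(!truth)[keep] / sum(!truth)),
    tpr = c(0, cumsum(truth)[keep] / sum(truth))
  )
}

#' Precision-recall curve points and area
#'
#' `pr_points()` walks the ranking from most to least confident and records
#' precision and recall at each distinct threshold; `aupr()` integrates the
#' curve in average-precision form (precision weighted by recall
#' increments).
#'
#' @inheritParams ts_precision
#' @return `pr_points()`: tibble of `(recall, precision)`; `aupr()`: area in
#'   \[0, 1\].
#' @export
pr_points <- function(truth, confidence) {
  truth <- check_truth(truth)
  check_two_class(truth, "PR curve")
  ord <- order(-confidence)
  truth <- truth[ord]
  conf <- confidence[ord]
  keep <- c(conf[-1] != conf[-length(conf)], TRUE)
  k <- which(keep)
  tibble::tibble(
    recall = cumsum(truth)[k] / sum(truth),
    precision = cumsum(truth)[k] / k
  )
}

#' @rdname pr_points
#' @export
aupr <- function(truth, confidence) {
  pts <- pr_points(truth, confidence)
  sum(diff(c(0, pts$recall)) * pts$precision)
}

#' Point-biserial correlation of confidence with a binary outcome
#'
#' (M1 - M0) / s_n * sqrt(p q), where M1/M0 are the mean confidences of the
#' positive/negative groups, s_n the population standard deviation of the
#' confidences, and p, q the group proportions. Identical to the Pearson
#' correlation of the confidences with the outcome coded 0/1.
#'
#' @inheritParams ts_precision
#' @return Correlation in \[-1, 1\]; 0 when the confidences are constant.
#' @export
point_biserial <- function(truth, confidence) {
  truth <- check_truth(truth)
  check_two_class(truth, "point-biserial correlation")
  n <- length(truth)
  s_n <- sqrt(sum((confidence - mean(confidence))^2) / n)
  if (s_n == 0) return(0)
  p <- mean(truth)
  (mean(confidence[truth]) - mean(confidence[!truth])) / s_n * sqrt(p * (1 - p))
}
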