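# Threshold-free and thresholded classification metrics.

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney pairwise-comparison statistic (ties counted
#' one half) via midranks, so it equals the exhaustive concordant-pair
#' fraction exactly.
#'
#' @param scores Numeric scores. @param labels 0/1 labels.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("AUROC undefined: labels contain one class")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-function average precision: sum over descending distinct score
#' thresholds of precision times the recall increment.
#'
#' @inheritParams auroc
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1)
  if (n_pos == 0 || n_pos == length(labels)) {
    stop("AUPRC undefined: labels contain one class")
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- c(s[-1] != s[-length(s)], TRUE)   # last index of each tie group
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  sum(prec * diff(c(0, rec)))
}

#' Youden's J optimal threshold
#'
#' Scans all observed scores as candidate cut-points (predict positive when
#' `score >= t`) and returns the one maximizing J = sensitivity +
#' specificity - 1; ties resolve to the lowest such threshold.
#'
#' @inheritParams auroc
#' @return The selected threshold.
#' @export
youden_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("Youden threshold undefined: one class")
  cand <- sort(unique(scores))
  j <- vapply(cand, function(t) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    sens + spec - 1
  }, numeric(1))
  cand[which.max(j)]
}

#' Thresholded and threshold-free performance metrics
#'
#' @inheritParams auroc
#' @param threshold Probability cut-point (predict positive when
#'   `score >= threshold`).
#' @return One-row tibble: auroc, auprc, precision, recall, accuracy, f1,
#'   specificity, threshold. For a binary task the micro-averaged F1 equals
#'   the standard positive-class F1 reported here. Precision is defined as 0
#'   when nothing is predicted positive.
#' @export
compute_metrics <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  tibble::tibble(auroc = auroc(scores, labels),
                 auprc = auprc(scores, labels),
                 precision = precision, recall = recall,
                 accuracy = (tp + tn) / length(labels), f1 = f1,
                 specificity = tn / (tn + fp), threshold = threshold)
}
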