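check_two_classes <- function(labels) {
  if (length(unique(labels)) < 2L) {
    ddi_stop("metric undefined: both classes must be present",
             "ddidock_undefined_metric_error")
  }
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney concordance probability: the chance that a
#' random positive scores above a random negative, with ties counted 1/2.
#'
#' @param scores numeric prediction scores (higher = more likely positive).
#' @param labels 0/1 labels.
#' @return fraction in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.numeric(labels)
  check_two_classes(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-wise average precision: precision integrated over the recall
#' increments at each unique score threshold (descending), which handles
#' tied scores without an arbitrary within-tie order.
#'
#' @inheritParams auroc
#' @return fraction in \[0, 1\].
#' @export
aupr <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  if (n_pos == 0L) {
    ddi_stop("AUPR undefined: no positive labels", "ddidock_undefined_metric_error")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  # collapse to unique thresholds: keep the last index of each tied block
  last <- which(c(s[-length(s)] != s[-1L], TRUE))
  tp <- tp[last]; fp <- fp[last]
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Squared-correlation pseudo R-squared
#'
#' The squared Pearson correlation between predicted probabilities (or
#' scores) and the 0/1 labels. Zero-variance scores return 0 by convention.
#'
#' @inheritParams auroc
#' @return fraction in \[0, 1\].
#' @export
pseudo_r2 <- function(scores, labels) {
  labels <- as.numeric(labels)
  check_two_classes(labels)
  if (stats::sd(scores) == 0) return(0)
  stats::cor(scores, labels)^2
}

confusion_metrics <- function(scores, labels, threshold) {
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  tn <- sum(!pred & labels == 0)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  sensitivity <- if (tp + fn == 0) 0 else tp / (tp + fn)
  list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    accuracy = (tp + tn) / length(labels),
    precision = precision,
    sensitivity = sensitivity,
    specificity = if (tn + fp == 0) 0 else tn / (tn + fp),
    f1 = if (precision + sensitivity == 0) 0
         else 2 * precision * sensitivity / (precision + sensitivity)
  )
}

#' Select the classification threshold maximizing the F-score
#'
#' Scans every unique score as a candidate threshold (predict positive when
#' score >= threshold) and returns the one maximizing
#' F1 = 2 * precision * sensitivity / (precision + sensitivity); ties are
#' broken toward the lowest threshold. The confusion-based metrics of the
#' returned [metric_set()] are computed at that threshold.
#'
#' @inheritParams auroc
#' @return list with `threshold`, `f1` and `metrics` (a `metric_set`).
#' @export
max_f_threshold <- function(scores, labels) {
  labels <- as.numeric(labels)
  check_two_classes(labels)
  cand <- sort(unique(scores))
  f1 <- vapply(cand, function(t) confusion_metrics(scores, labels, t)$f1, 0.0)
  best <- cand[which(f1 == max(f1))[1L]]   # cand ascending -> lowest threshold
  list(threshold = best, f1 = max(f1),
       metrics = metric_set(scores, labels, best))
}

#' Full evaluation metric set at a threshold
#'
#' AUROC, AUPR and pseudo R-squared are threshold-free; accuracy, precision,
#' sensitivity and specificity come from the confusion table at `threshold`
#' (predict positive when score >= threshold).
#'
#' @inheritParams auroc
#' @param threshold probability/score cutoff.
#' @return An object of class `metric_set`: named list with `auroc`, `aupr`,
#'   `accuracy`, `precision`, `sensitivity`, `specificity`, `r2`, `f1`,
#'   `threshold`.
#' @export
metric_set <- function(scores, labels, threshold) {
  labels <- as.numeric(labels)
  check_two_classes(labels)
  cm <- confusion_metrics(scores, labels, threshold)
  structure(
    list(
      auroc = auroc(scores, labels),
      aupr = aupr(scores, labels),
      accuracy = cm$accuracy,
      precision = cm$precision,
      sensitivity = cm$sensitivity,
      specificity = cm$specificity,
      r2 = pseudo_r2(scores, labels),
      f1 = cm$f1,
      threshold = threshold
    ),
    class = "metric_set"
  )
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf(
    "<metric_set> AUROC %.3f  AUPR %.3f  acc %.3f  prec %.3f  sens %.3f  spec %.3f  R2 %.3f @ thr %.4f\n",
    x$auroc, x$aupr, x$accuracy, x$precision, x$sensitivity, x$specificity,
    x$r2, x$threshold))
  invisible(x)
}
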