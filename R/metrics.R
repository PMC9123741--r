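#' @name metrics
#' @title Binary classification metrics
#'
#' @description
#' The metric suite used to judge the classifier: confusion matrix,
#' precision, recall, accuracy, balanced accuracy, Matthews correlation
#' coefficient, ROC AUC (computed from the Mann-Whitney rank statistic with
#' midranks for ties) and average precision (the step-wise integral of the
#' precision-recall curve), plus the ROC and PR curve points.
NULL

#' ROC AUC from scores and labels
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels.
#' @return AUC in `[0, 1]`, or `NA` if only one class is present.
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels == 1L
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision (step-wise PR integral)
#'
#' `AP = sum_k (R_k - R_(k-1)) * P_k` over thresholds placed at each unique
#' score, descending; tied scores enter as one step.
#'
#' @inheritParams roc_auc
#' @return AP in `[0, 1]`, or `NA` if no positives.
#' @export
average_precision <- function(scores, labels) {
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L) return(NA_real_)
  thr <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0
  ap <- 0
  for (t in thr) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1L)
    prec <- tp / sum(sel)
    rec <- tp / n_pos
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

#' ROC curve points
#' @inheritParams roc_auc
#' @return data frame with `threshold`, `fpr`, `tpr` (thresholds at each
#'   unique score, descending, plus the all-negative end point).
#' @export
roc_curve <- function(scores, labels) {
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  do.call(rbind, lapply(thr, function(t) {
    sel <- scores >= t
    data.frame(threshold = t,
               fpr = if (n0) sum(labels[sel] == 0L) / n0 else NA_real_,
               tpr = if (n1) sum(labels[sel] == 1L) / n1 else NA_real_)
  }))
}

#' Precision-recall curve points
#' @inheritParams roc_auc
#' @return data frame with `threshold`, `recall`, `precision`.
#' @export
pr_curve <- function(scores, labels) {
  n1 <- sum(labels == 1L)
  thr <- sort(unique(scores), decreasing = TRUE)
  do.call(rbind, lapply(thr, function(t) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1L)
    data.frame(threshold = t,
               recall = if (n1) tp / n1 else NA_real_,
               precision = tp / sum(sel))
  }))
}

#' Full metrics report at a decision threshold
#'
#' Classes are assigned by `score >= threshold` ("0.98 or higher" semantics).
#' Precision is reported as 0 with `precision_defined = FALSE` when nothing
#' is predicted positive; AUC/AP are `NA` when undefined on a single-class
#' input.
#'
#' @param scores numeric prediction probabilities.
#' @param labels 0/1 labels.
#' @param threshold decision cut in (0, 1].
#' @return list of class `xt_metrics`.
#' @export
metrics_report <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels), length(scores) > 0L)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  precision_defined <- (tp + fp) > 0L
  precision <- if (precision_defined) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  tnr <- if (tn + fp > 0L) tn / (tn + fp) else NA_real_
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else 0
  structure(list(
    threshold = threshold,
    confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
    precision = precision, precision_defined = precision_defined,
    recall = recall,
    accuracy = (tp + tn) / length(labels),
    balanced_accuracy = mean(c(recall, tnr)),
    mcc = mcc,
    roc_auc = roc_auc(scores, labels),
    average_precision = average_precision(scores, labels),
    roc = roc_curve(scores, labels),
    pr = pr_curve(scores, labels)),
    class = "xt_metrics")
}

#' @export
print.xt_metrics <- function(x, ...) {
  cat(sprintf(
    "Metrics @ threshold %.3g: TP=%d FP=%d TN=%d FN=%d\n",
    x$threshold, x$confusion[["TP"]], x$confusion[["FP"]],
    x$confusion[["TN"]], x$confusion[["FN"]]))
  cat(sprintf(
    "  precision=%.4f recall=%.4f accuracy=%.4f bal.acc=%.4f MCC=%.4f\n",
    x$precision, x$recall, x$accuracy, x$balanced_accuracy, x$mcc))
  cat(sprintf("  ROC AUC=%.4f  average precision=%.4f\n",
              x$roc_auc, x$average_precision))
  invisible(x)
}
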