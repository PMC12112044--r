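# Binary classification metrics: the eight-metric evaluation protocol
# (accuracy, sensitivity, specificity, MCC, ROC-AUC, F1, balanced
# accuracy, PR-AUC). Threshold metrics use the 0.5 decision rule on
# sigmoid scores; ranking metrics use the raw scores.

#' Eight-metric classification report
#'
#' Computes the confusion-matrix metrics at the given threshold plus
#' ROC-AUC (trapezoidal rule over the ROC curve) and PR-AUC (step
#' interpolation of the precision-recall curve). With a single observed
#' class the ranking metrics are `NA` (undefined), not zero.
#'
#' @param scores numeric vector of predicted probabilities (or any
#'   monotone ranking scores for the AUCs).
#' @param labels 0/1 vector of true labels.
#' @param threshold decision threshold on `scores` (default 0.5).
#' @return a `metrics_report`: list with `accuracy`, `sensitivity`,
#'   `specificity`, `mcc`, `auc_roc`, `f1`, `balanced_accuracy`, `auc_pr`,
#'   the confusion counts `tp`, `fp`, `tn`, `fn`, and `n_pos`, `n_neg`.
#' @export
metrics_report <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels), length(scores) > 0)
  labels <- as.integer(labels > 0.5)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  n_pos <- tp + fn; n_neg <- tn + fp
  div <- function(a, b) if (b > 0) a / b else NA_real_
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else NA_real_
  f1 <- div(2 * tp, 2 * tp + fp + fn)
  structure(list(
    accuracy = (tp + tn) / length(labels),
    sensitivity = sens, specificity = spec, mcc = mcc,
    auc_roc = roc_auc(scores, labels),
    f1 = f1,
    balanced_accuracy = if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2,
    auc_pr = pr_auc(scores, labels),
    tp = tp, fp = fp, tn = tn, fn = fn, n_pos = n_pos, n_neg = n_neg
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("accuracy %.4f | sens %.4f | spec %.4f | MCC %.4f | ",
                     "ROC-AUC %.4f | F1 %.4f | bal.acc %.4f | PR-AUC %.4f ",
                     "(n+ %d, n- %d)\n"),
              x$accuracy, x$sensitivity, x$specificity, x$mcc, x$auc_roc,
              x$f1, x$balanced_accuracy, x$auc_pr, x$n_pos, x$n_neg))
  invisible(x)
}

# ROC curve points at every distinct score threshold, descending
.roc_points <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp_end <- which(c(diff(s) != 0, TRUE))      # last index of each tie group
  tp <- cumsum(y)[grp_end]
  fp <- cumsum(1 - y)[grp_end]
  list(tpr = c(0, tp / sum(y)), fpr = c(0, fp / sum(1 - y)),
       tp = c(0, tp), fp = c(0, fp))
}

#' Area under the ROC curve (trapezoidal rule)
#'
#' @param scores ranking scores, higher = more positive.
#' @param labels 0/1 labels.
#' @return AUC in \[0, 1\], or `NA` when only one class is present.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels > 0.5)
  if (sum(labels) == 0 || sum(labels) == length(labels)) return(NA_real_)
  pts <- .roc_points(scores, labels)
  sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
}

#' Area under the precision-recall curve (step interpolation)
#'
#' Right-continuous step interpolation over the distinct score
#' thresholds: each recall increment contributes the precision attained
#' at that threshold.
#'
#' @inheritParams roc_auc
#' @return PR-AUC in \[0, 1\], or `NA` when only one class is present.
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.integer(labels > 0.5)
  n_pos <- sum(labels)
  if (n_pos == 0 || n_pos == length(labels)) return(NA_real_)
  pts <- .roc_points(scores, labels)
  tp <- pts$tp[-1]; fp <- pts$fp[-1]
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}
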