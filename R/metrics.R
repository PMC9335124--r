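# Binary-classifier evaluation: confusion counts, the six threshold
# metrics (Sn, Sp, Pr, F1, Acc, MCC), and the two ranking metrics
# (AUROC, AUPRC).

#' Confusion counts for binary predictions
#'
#' @param y_true,y_pred Equal-length binary label vectors (logical, 0/1,
#'   two-level factor, or "positive"/"negative" strings).
#' @return Named integer vector `c(TP, FP, TN, FN)`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) == 0) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  yt <- as_binary_labels(y_true)
  yp <- as_binary_labels(y_pred)
  c(TP = sum(yt == 1 & yp == 1), FP = sum(yt == 0 & yp == 1),
    TN = sum(yt == 0 & yp == 0), FN = sum(yt == 1 & yp == 0))
}

#' Threshold classification metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)`, F1 `2TP/(2TP+FP+FN)`, accuracy, and the Matthews
#' correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Any metric with a zero denominator is reported as 0 with a warning, so
#' fold averaging never propagates NaN.
#'
#' @param cm Named vector with elements TP, FP, TN, FN (as from
#'   [confusion_counts()]).
#' @return Named numeric vector `c(Sn, Sp, Pr, F1, Acc, MCC)`.
#' @export
scalar_metrics <- function(cm) {
  tp <- as.numeric(cm[["TP"]]); fp <- as.numeric(cm[["FP"]])
  tn <- as.numeric(cm[["TN"]]); fn <- as.numeric(cm[["FN"]])
  safe_div <- function(num, den, name) {
    if (den == 0) {
      warning(name, " undefined (zero denominator); reporting 0")
      return(0)
    }
    num / den
  }
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  c(Sn = safe_div(tp, tp + fn, "Sn"),
    Sp = safe_div(tn, tn + fp, "Sp"),
    Pr = safe_div(tp, tp + fp, "Pr"),
    F1 = safe_div(2 * tp, 2 * tp + fp + fn, "F1"),
    Acc = safe_div(tp + tn, tp + fp + tn + fn, "Acc"),
    MCC = safe_div(tp * tn - fp * fn, mcc_den, "MCC"))
}

#' Area under the ROC curve
#'
#' Computed by the rank (Mann-Whitney) method: the probability that a
#' randomly chosen positive scores above a randomly chosen negative, with
#' ties counted half.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary true labels (both classes must be present).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision: `sum_k (R_k - R_{k-1}) * P_k` over
#' descending distinct score thresholds, with no linear interpolation.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary true labels (at least one positive).
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n_pos <- sum(y == 1)
  if (n_pos == 0) stop("at least one positive required")
  ord <- order(-scores)
  s <- scores[ord]; y <- y[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  # evaluate only at the last index of each tied score block
  last_of_block <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[last_of_block]; fp <- fp[last_of_block]
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Full metric report from scores and labels
#'
#' Thresholds `scores` at `tp` for the six confusion metrics and adds the
#' two ranking metrics.
#'
#' @param scores Numeric prediction scores in `[0, 1]`.
#' @param labels Binary true labels.
#' @param tp Probability threshold; a peptide scoring `>= tp` is predicted
#'   a binder (default 0.5).
#' @return Named numeric vector with Sn, Sp, Pr, F1, Acc, MCC, AUROC, AUPRC.
#' @export
metric_report <- function(scores, labels, tp = 0.5) {
  cm <- confusion_counts(labels, scores >= tp)
  c(scalar_metrics(cm),
    AUROC = auroc(scores, labels),
    AUPRC = auprc(scores, labels))
}
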