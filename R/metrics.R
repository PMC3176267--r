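#' Confusion counts for binary labels
#'
#' Tallies true/false positives and negatives for labels in `{+1, -1}`,
#' with `+1` the positive class.
#'
#' @param y_true,y_pred Equal-length vectors of labels in `{+1, -1}`.
#' @return A list of class `confusion_counts` with integer fields `TP`,
#'   `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 1L)
    stop("y_true and y_pred must have equal length >= 1")
  if (!all(y_true %in% c(-1, 1)) || !all(y_pred %in% c(-1, 1)))
    stop_format("labels must be +1 or -1")
  structure(list(
    TP = sum(y_true == 1 & y_pred == 1),
    FP = sum(y_true == -1 & y_pred == 1),
    TN = sum(y_true == -1 & y_pred == -1),
    FN = sum(y_true == 1 & y_pred == -1)), class = "confusion_counts")
}

#' Accuracy, sensitivity, specificity and MCC from confusion counts
#'
#' Standard binary-classification metrics:
#' \deqn{Accuracy = (TP+TN)/(TP+FP+TN+FN)}
#' \deqn{Sensitivity = TP/(TP+FN), \quad Specificity = TN/(TN+FP)}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) /
#'   \sqrt{(TP+FP)(TN+FN)(TP+FN)(TN+FP)}}
#' Accuracy, sensitivity and specificity are returned in percent; MCC lies
#' in `[-1, 1]` (`1` is perfect prediction, `-1` perfect anti-correlation,
#' `0` is the random-prediction expectation). When any marginal of the MCC
#' denominator is zero, MCC is reported as 0 with `mcc_undefined = TRUE`
#' and a warning.
#'
#' @param counts A [confusion_counts()] object (or list with `TP`, `FP`,
#'   `TN`, `FN`).
#' @return A list with `counts`, `accuracy`, `sensitivity`, `specificity`
#'   (percent), `mcc`, and the flag `mcc_undefined`.
#' @examples
#' classification_metrics(list(TP = 105, FP = 30, TN = 160, FN = 36))
#' @export
classification_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  stopifnot(all(c(TP, FP, TN, FN) >= 0))
  n <- TP + FP + TN + FN
  if (n == 0L) stop("no observations")
  denom2 <- as.numeric(TP + FP) * (TN + FN) * (TP + FN) * (TN + FP)
  mcc_undefined <- denom2 == 0
  if (mcc_undefined) {
    warning("MCC denominator is zero; reporting MCC = 0")
    mcc <- 0
  } else {
    mcc <- (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(denom2)
  }
  list(counts = counts,
       accuracy = 100 * (TP + TN) / n,
       sensitivity = if (TP + FN > 0) 100 * TP / (TP + FN) else NA_real_,
       specificity = if (TN + FP > 0) 100 * TN / (TN + FP) else NA_real_,
       mcc = mcc,
       mcc_undefined = mcc_undefined)
}

#' ROC curve from decision values
#'
#' Sweeps a threshold over the sorted unique decision values (ties
#' grouped), producing (false positive rate, true positive rate) points
#' from `(0, 0)` to `(1, 1)`.
#'
#' @param decision_values Numeric scores; larger means more positive.
#' @param y_true Labels in `{+1, -1}`, both classes present.
#' @return A data frame with columns `fpr` and `tpr`.
#' @export
roc_points <- function(decision_values, y_true) {
  if (length(decision_values) != length(y_true))
    stop("decision_values and y_true must align")
  if (!all(y_true %in% c(-1, 1)) || length(unique(y_true)) < 2L)
    stop("both classes must be present with labels +1/-1")
  pos <- y_true == 1
  n_pos <- sum(pos); n_neg <- sum(!pos)
  o <- order(decision_values, decreasing = TRUE)
  dv <- decision_values[o]; p <- pos[o]
  tp <- cumsum(p); fp <- cumsum(!p)
  keep <- c(dv[-1] != dv[-length(dv)], TRUE)  # last index of each tie group
  data.frame(fpr = c(0, fp[keep] / n_neg), tpr = c(0, tp[keep] / n_pos))
}

#' Area under the ROC curve
#'
#' Trapezoid-rule area under [roc_points()]; in the absence of ties this
#' equals the normalized Mann-Whitney U statistic
#' (concordant pairs + half the tied pairs) / (n_pos * n_neg).
#'
#' @param points A data frame from [roc_points()], or decision values (in
#'   which case `y_true` must be given).
#' @param y_true Optional labels, to compute the curve first.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(points, y_true = NULL) {
  if (!is.null(y_true)) points <- roc_points(points, y_true)
  x <- points$fpr; y <- points$tpr
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Full evaluation report for a set of predictions
#'
#' Convenience wrapper combining [confusion_counts()],
#' [classification_metrics()] and, when decision values are supplied,
#' [roc_points()] and [roc_auc()].
#'
#' @param y_true True labels in `{+1, -1}`.
#' @param y_pred Predicted labels.
#' @param decision_values Optional decision scores for the ROC/AUC.
#' @return A list of class `evaluation_report`.
#' @export
evaluation_report <- function(y_true, y_pred, decision_values = NULL) {
  metrics <- classification_metrics(confusion_counts(y_true, y_pred))
  if (!is.null(decision_values)) {
    metrics$roc <- roc_points(decision_values, y_true)
    metrics$auc <- roc_auc(metrics$roc)
  }
  class(metrics) <- "evaluation_report"
  metrics
}

#' @export
print.evaluation_report <- function(x, ...) {
  with(x, cat(sprintf(
    "<evaluation_report> acc %.2f%% | sens %.2f%% | spec %.2f%% | MCC %.4f%s\n",
    accuracy, sensitivity, specificity, mcc,
    if (!is.null(x$auc)) sprintf(" | AUC %.3f", auc) else "")))
  invisible(x)
}
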