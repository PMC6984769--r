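#' Confusion counts from predicted and true labels
#'
#' @param pred,truth Binary vectors (0/1) of equal length.
#' @return Named integer vector `c(TP, FP, TN, FN)`.
#' @export
confusion_counts <- function(pred, truth) {
  stopifnot(length(pred) == length(truth),
            all(pred %in% c(0, 1)), all(truth %in% c(0, 1)))
  c(TP = sum(pred == 1 & truth == 1),
    FP = sum(pred == 1 & truth == 0),
    TN = sum(pred == 0 & truth == 0),
    FN = sum(pred == 0 & truth == 1))
}

#' Confusion-matrix performance metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/total`, and Matthews correlation
#' `(TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN))`.  When any
#' factor of the MCC denominator is zero the coefficient is undefined;
#' the convention here is to return 0 (an uninformative classifier)
#' with a warning.  Sens (resp. Spec) is `NA` when there are no
#' positives (resp. negatives).
#'
#' @param counts Named vector with entries `TP`, `FP`, `TN`, `FN`
#'   (e.g. from [confusion_counts()]); alternatively give the four
#'   counts via the named arguments.
#' @param TP,FP,TN,FN Individual counts, used when `counts` is missing.
#' @return A list with elements `Sens`, `Spec`, `ACC`, `MCC` and the
#'   counts.
#' @examples
#' compute_metrics(TP = 1092, FP = 0, TN = 0, FN = 357)$ACC  # 0.7536 (4 d.p.)
#' @export
compute_metrics <- function(counts = NULL, TP = NULL, FP = NULL,
                            TN = NULL, FN = NULL) {
  if (!is.null(counts)) {
    TP <- counts[["TP"]]; FP <- counts[["FP"]]
    TN <- counts[["TN"]]; FN <- counts[["FN"]]
  }
  total <- TP + FP + TN + FN
  if (total == 0) stop("all confusion counts are zero")
  sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  spec <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  acc <- (TP + TN) / total
  denom2 <- as.numeric(TP + FN) * (TP + FP) * (TN + FP) * (TN + FN)
  if (denom2 == 0) {
    warning("MCC denominator is zero; returning 0")
    mcc <- 0
  } else {
    mcc <- (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(denom2)
  }
  list(Sens = sens, Spec = spec, ACC = acc, MCC = mcc,
       counts = c(TP = TP, FP = FP, TN = TN, FN = FN))
}

#' Area under the ROC curve (rank statistic)
#'
#' AUC computed as the Mann-Whitney statistic: the probability that a
#' randomly chosen positive outscores a randomly chosen negative, with
#' ties counted half.  Invariant under strictly monotone transforms of
#' the scores.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1), same length.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_rank(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))  # 0.75
#' @export
auc_rank <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' Sweeps the score thresholds from high to low and records the false-
#' and true-positive rates, collapsing tied scores into single steps.
#' The curve runs monotonically from `(0, 0)` to `(1, 1)`.
#'
#' @inheritParams auc_rank
#' @return A `data.frame` with columns `threshold`, `fpr`, `tpr`;
#'   the leading `(0, 0)` point carries threshold `Inf`.
#' @export
roc_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  lab <- labels[o]
  keep <- c(s[-length(s)] != s[-1], TRUE)  # last index of each tied run
  tp <- cumsum(lab == 1)[keep]
  fp <- cumsum(lab == 0)[keep]
  data.frame(threshold = c(Inf, s[keep]),
             fpr = c(0, fp / n_neg),
             tpr = c(0, tp / n_pos))
}
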