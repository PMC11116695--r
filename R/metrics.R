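#' Confusion counts of binary predictions
#'
#' @param labels True labels (0/1).
#' @param predicted Predicted labels (0/1).
#' @return A tibble with integer columns `TP`, `FP`, `TN`, `FN`
#'   (summing to `length(labels)`).
#' @export
confusion <- function(labels, predicted) {
  if (length(labels) != length(predicted)) {
    stop("labels and predictions have different lengths", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1)) || !all(predicted %in% c(0, 1))) {
    stop("labels and predictions must be binary 0/1", call. = FALSE)
  }
  tibble::tibble(
    TP = sum(labels == 1 & predicted == 1),
    FP = sum(labels == 0 & predicted == 1),
    TN = sum(labels == 0 & predicted == 0),
    FN = sum(labels == 1 & predicted == 0)
  )
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, recall, F1 and the Matthews correlation
#' coefficient. A metric whose denominator is zero is reported as `NA`
#' (undefined), never silently as 0.
#'
#' @param c A one-row data frame with columns `TP`, `FP`, `TN`, `FN`
#'   (see [confusion()]).
#' @return A one-row tibble with columns `acc`, `prec`, `rec`, `f1`, `mcc`.
#' @examples
#' metrics(tibble::tibble(TP = 40, FP = 15, TN = 35, FN = 10))
#' @export
metrics <- function(c) {
  stopifnot(all(c(c$TP, c$FP, c$TN, c$FN) >= 0))
  tp <- as.double(c$TP)
  fp <- as.double(c$FP)
  tn <- as.double(c$TN)
  fn <- as.double(c$FN)
  n <- tp + fp + tn + fn
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  acc <- safe_div(tp + tn, n)
  prec <- safe_div(tp, tp + fp)
  rec <- safe_div(tp, tp + fn)
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) {
    NA_real_
  } else {
    2 * prec * rec / (prec + rec)
  }
  mcc_den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / sqrt(mcc_den)
  tibble::tibble(acc = acc, prec = prec, rec = rec, f1 = f1, mcc = mcc)
}

#' Area under the ROC curve
#'
#' Computed by the rank statistic (equivalent to the probability that a
#' random positive outscores a random negative, ties counted half), which
#' is exact and handles tied scores.
#'
#' @param labels True labels (0/1), both classes present.
#' @param scores Real-valued scores (higher = more positive).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  check_two_class(labels, scores)
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  r <- rank(scores) # average ranks on ties
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the precision-recall curve
#'
#' Step integration of precision over recall: thresholds sweep the distinct
#' scores in descending order (tied scores enter together) and each recall
#' increment contributes at the precision reached there.
#'
#' @inheritParams roc_auc
#' @return AUPR in `(0, 1]`.
#' @export
pr_auc <- function(labels, scores) {
  check_two_class(labels, scores)
  npos <- sum(labels == 1)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  # group tied scores so a threshold admits all of them at once
  grp <- cumsum(!duplicated(sc))
  tp <- cumsum(lab)
  fp <- cumsum(1 - lab)
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- tp[last]
  fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / npos
  sum(diff(c(0, rec)) * prec)
}

check_two_class <- function(labels, scores) {
  if (length(labels) != length(scores)) {
    stop("labels and scores have different lengths", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) != 2L) {
    stop("labels must contain both classes (0 and 1)", call. = FALSE)
  }
  invisible(TRUE)
}

#' ROC and precision-recall curve points
#'
#' @inheritParams roc_auc
#' @return A tibble with columns `threshold`, `fpr`, `tpr`, `precision`,
#'   `recall`, one row per distinct score (descending).
#' @export
roc_pr_points <- function(labels, scores) {
  check_two_class(labels, scores)
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  grp <- cumsum(!duplicated(sc))
  tp <- cumsum(lab)
  fp <- cumsum(1 - lab)
  last <- !duplicated(grp, fromLast = TRUE)
  tibble::tibble(
    threshold = sc[last],
    fpr = fp[last] / nneg,
    tpr = tp[last] / npos,
    precision = tp[last] / (tp[last] + fp[last]),
    recall = tp[last] / npos
  )
}
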