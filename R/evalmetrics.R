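# Classification, regression, screening-quality, and correlation statistics
# shared by the baseline, few-shot and selector modules. Active = positive
# throughout. All zero-denominator cases return 0 by convention so that
# degenerate predictions (e.g. "no positives called") yield a defined report.

#' Confusion table of binary predictions
#'
#' @param y_true,y_pred 0/1 vectors of equal length (active = 1 = positive).
#' @return list with integer fields TP, TN, FP, FN.
#' @export
#' @examples
#' confusion(c(1, 1, 0, 0), c(1, 0, 0, 0))
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length", call. = FALSE)
  stopifnot(all(y_true %in% 0:1), all(y_pred %in% 0:1))
  list(TP = sum(y_true == 1 & y_pred == 1),
       TN = sum(y_true == 0 & y_pred == 0),
       FP = sum(y_true == 0 & y_pred == 1),
       FN = sum(y_true == 1 & y_pred == 0))
}

safe_div <- function(num, den) if (den == 0) 0 else num / den

#' Threshold classification metrics from a confusion table
#'
#' Precision, recall, specificity, accuracy, F1, Cohen's kappa and the
#' Matthews correlation coefficient. MCC uses
#' (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)); kappa is
#' (p_o - p_e) / (1 - p_e). Any zero denominator yields 0.
#'
#' @param tab a confusion table from [confusion()].
#' @return named list of metrics.
#' @export
classification_metrics <- function(tab) {
  TP <- tab$TP; TN <- tab$TN; FP <- tab$FP; FN <- tab$FN
  n <- TP + TN + FP + FN
  stopifnot(n >= 1)
  precision <- safe_div(TP, TP + FP)
  recall <- safe_div(TP, TP + FN)
  specificity <- safe_div(TN, TN + FP)
  accuracy <- (TP + TN) / n
  f1 <- safe_div(2 * precision * recall, precision + recall)
  p_o <- accuracy
  p_e <- ((TP + FP) * (TP + FN) + (TN + FN) * (TN + FP)) / n^2
  kappa <- safe_div(p_o - p_e, 1 - p_e)
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  mcc <- if (mcc_den == 0) 0 else (TP * TN - FP * FN) / mcc_den
  list(precision = precision, recall = recall, specificity = specificity,
       accuracy = accuracy, f1 = f1, kappa = kappa, mcc = mcc)
}

#' ROC AUC via the rank statistic
#'
#' Computed as the Mann-Whitney statistic with midrank tie correction:
#' the probability that a random active scores above a random inactive,
#' counting ties as one half.
#'
#' @param scores numeric prediction scores (larger = more active).
#' @param labels 0/1 truth labels; both classes must be present.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present for ROC AUC", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Average precision (area under the precision-recall curve)
#'
#' Step-interpolated definition: AP = sum over ranked positives of
#' (recall step) x (precision at that rank). Ties in scores are grouped so
#' the result does not depend on the order of equal-scored records.
#'
#' @inheritParams roc_auc
#' @return average precision in [0, 1].
#' @export
avg_precision <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n_pos <- sum(labels == 1)
  if (n_pos == 0 || all(labels == 1))
    stop("both classes must be present for average precision", call. = FALSE)
  # process tied scores as a block: cumulative counts at block boundaries
  ord <- order(-scores)
  s <- scores[ord]; y <- labels[ord]
  block <- cumsum(!duplicated(s))
  tp_cum <- cumsum(y); all_cum <- seq_along(y)
  last_of_block <- !duplicated(block, fromLast = TRUE)
  tp_b <- tp_cum[last_of_block]
  all_b <- all_cum[last_of_block]
  prec <- tp_b / all_b
  rec <- tp_b / n_pos
  sum(prec * diff(c(0, rec)))
}

#' Coefficient of determination
#'
#' R^2 = 1 - SS_res / SS_tot against the mean of the truth.
#'
#' @param y_true,y_pred numeric vectors, length >= 2.
#' @return R^2 (can be negative for models worse than the mean).
#' @export
r_squared <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2)
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0)
    stop("zero variance in y_true: R^2 undefined", call. = FALSE)
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Z'-factor plate quality statistic
#'
#' Z' = 1 - 3(sigma_p + sigma_n) / |mu_p - mu_n|, the standard screening
#' window statistic from positive/negative control wells.
#'
#' @param mu_p,sigma_p positive-control mean and sd.
#' @param mu_n,sigma_n negative-control mean and sd.
#' @return Z' (<= 1; values above ~0.5 indicate an excellent assay window).
#' @export
#' @examples
#' z_prime(100, 5, 0, 5)  # 0.7
z_prime <- function(mu_p, sigma_p, mu_n, sigma_n) {
  stopifnot(sigma_p >= 0, sigma_n >= 0)
  if (mu_p == mu_n)
    stop("Z' undefined for equal control means", call. = FALSE)
  1 - 3 * (sigma_p + sigma_n) / abs(mu_p - mu_n)
}

#' Sample Pearson correlation
#'
#' @param x,y numeric vectors of equal length >= 3 with positive variance.
#' @return correlation in [-1, 1].
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  stats::cor(x, y)
}

#' Full metric report for scored binary predictions
#'
#' Threshold metrics at 0.5 (or a supplied threshold on the score scale)
#' plus ROC AUC and average precision.
#'
#' @param labels 0/1 truth.
#' @param scores prediction scores in any monotone scale.
#' @param threshold score cut for the thresholded metrics.
#' @return named list: rocauc, avg_precision, f1, ck, mcc, precision,
#'   recall, specificity, accuracy (key names mirror the reporting layout
#'   used throughout the package).
#' @export
metric_report <- function(labels, scores, threshold = 0.5) {
  cm <- classification_metrics(confusion(labels,
                                         as.integer(scores >= threshold)))
  list(rocauc = roc_auc(scores, labels),
       avg_precision = avg_precision(scores, labels),
       f1 = cm$f1, ck = cm$kappa, mcc = cm$mcc,
       precision = cm$precision, recall = cm$recall,
       specificity = cm$specificity, accuracy = cm$accuracy)
}
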