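# Evaluation statistics: AUC, accuracy, F1, R^2, RMSE, MAPE and
# Cronbach's alpha.

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Probability that a randomly chosen positive receives a higher score than a
#' randomly chosen negative, ties counting one half. Computed from the rank
#' sum, which is exactly the pairwise definition.
#'
#' @param labels binary vector (0/1 or logical).
#' @param scores numeric scores, higher means more positive.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) stop("length mismatch")
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC needs at least one positive and one negative label")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Classification accuracy
#' @param labels,predictions binary vectors of equal length.
#' @return fraction of agreements.
#' @export
accuracy <- function(labels, predictions) {
  if (length(labels) != length(predictions)) stop("length mismatch")
  mean(as.integer(labels) == as.integer(predictions))
}

#' F1 score of the positive class
#'
#' Harmonic mean of precision and recall; defined as 0 when
#' precision + recall is 0 (the all-negative-prediction convention).
#'
#' @param labels,predictions binary vectors of equal length.
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(labels, predictions) {
  if (length(labels) != length(predictions)) stop("length mismatch")
  labels <- as.integer(labels); predictions <- as.integer(predictions)
  tp <- sum(labels == 1L & predictions == 1L)
  fp <- sum(labels == 0L & predictions == 1L)
  fn <- sum(labels == 1L & predictions == 0L)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}

#' Coefficient of determination
#' @param y observed values (must not be constant).
#' @param yhat predictions.
#' @return `1 - SS_res / SS_tot` (can be negative; 1 iff exact fit).
#' @export
r_squared <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("r_squared undefined for constant y")
  1 - sum((y - yhat)^2) / ss_tot
}

#' Root mean square error
#' @param y,yhat numeric vectors of equal length.
#' @return `sqrt(mean((y - yhat)^2))`.
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  sqrt(mean((y - yhat)^2))
}

#' Mean absolute percentage error
#'
#' `100 * mean(|y - yhat| / |y|)` over admissible entries. Converted scores
#' hit exactly 0 at the Likert floor, where the percentage error is
#' undefined; the default policy excludes such entries (the number excluded
#' is attached as attribute `"n_excluded"`), the alternative offsets the
#' denominator by `eps`.
#'
#' @param y,yhat numeric vectors of equal length.
#' @param zero_policy `"exclude"` (default) or `"epsilon"`.
#' @param eps denominator offset under `zero_policy = "epsilon"`.
#' @return MAPE in percent.
#' @export
mape <- function(y, yhat, zero_policy = c("exclude", "epsilon"), eps = 1e-6) {
  zero_policy <- match.arg(zero_policy)
  if (length(y) != length(yhat)) stop("length mismatch")
  if (zero_policy == "exclude") {
    keep <- y != 0
    if (!any(keep)) stop("all entries excluded by zero_policy")
    out <- 100 * mean(abs(y[keep] - yhat[keep]) / abs(y[keep]))
    attr(out, "n_excluded") <- sum(!keep)
    out
  } else {
    100 * mean(abs(y - yhat) / (abs(y) + eps))
  }
}

#' Cronbach's alpha internal-consistency coefficient
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(item sums))` for k
#' items. For k parallel items with common inter-item correlation rho this
#' approaches the Spearman-Brown value `k*rho / (1 + (k-1)*rho)`.
#'
#' @param item_matrix numeric matrix, respondents x items (k >= 2 columns,
#'   >= 2 rows).
#' @return alpha (at most 1; can be negative).
#' @export
cronbach_alpha <- function(item_matrix) {
  x <- as.matrix(item_matrix)
  k <- ncol(x)
  if (k < 2 || nrow(x) < 2) stop("need at least 2 items and 2 respondents")
  total_var <- stats::var(rowSums(x))
  if (total_var == 0) stop("degenerate (zero) total-score variance")
  k / (k - 1) * (1 - sum(apply(x, 2, stats::var)) / total_var)
}
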