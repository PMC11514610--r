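check_two_classes <- function(labels) {
  if (length(unique(labels)) < 2) {
    stop("metric undefined: both presence and background labels are ",
         "required", call. = FALSE)
  }
}

#' Area under the ROC curve
#'
#' Rank-statistic definition: the probability that a uniformly drawn
#' presence outscores a uniformly drawn background point, ties counted 1/2.
#'
#' @param scores Numeric scores in `[0, 1]`.
#' @param labels 0/1 labels (1 = presence).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  check_two_classes(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores)                       # average ranks handle ties as 1/2
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' True skill statistic at a threshold
#'
#' `TSS = sensitivity + specificity - 1`, with presence predicted when
#' `score >= threshold`.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @param threshold Binarization threshold in `[0, 1]`.
#' @return TSS in `[-1, 1]`.
#' @export
tss <- function(scores, labels, threshold) {
  stopifnot(length(scores) == length(labels))
  check_two_classes(labels)
  pred <- scores >= threshold
  sens <- sum(pred & labels == 1) / sum(labels == 1)
  spec <- sum(!pred & labels == 0) / sum(labels == 0)
  sens + spec - 1
}

#' Maximum sensitivity-specificity-sum threshold
#'
#' Scans the distinct observed scores as candidate thresholds and returns
#' the one maximizing sensitivity + specificity (equivalently TSS); ties go
#' to the smallest threshold.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @return The selected threshold.
#' @export
mss_threshold <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  check_two_classes(labels)
  cand <- sort(unique(scores))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  ## at threshold t: predicted presence iff score >= t; walking candidates
  ## upward, counts of scores >= t are suffix sums over the sorted values
  tss_at <- vapply(cand, function(t) {
    pred <- scores >= t
    sum(pred & labels == 1) / n1 + sum(!pred & labels == 0) / n0 - 1
  }, numeric(1))
  cand[which.max(tss_at)]                  # which.max takes the first max
}
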