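#' ROC curve over all candidate thresholds
#'
#' Enumerates one operating point per candidate threshold: the midpoints
#' between consecutive sorted unique scores, plus `-Inf` and `+Inf`
#' sentinels (so the endpoints (Se=1, Sp=0) and (Se=0, Sp=1) are always
#' present). The positive-call convention is `score >= threshold`
#' throughout the package.
#'
#' @param scores Numeric scores, higher = more likely positive.
#' @param labels Binary labels (0/1), both classes present.
#' @return Data frame of class `roc_curve` with columns `threshold`,
#'   `sensitivity`, `specificity`, ordered by increasing threshold.
#' @export
roc_points <- function(scores, labels) {
  labels <- check_binary(labels, scores)
  thresholds <- candidate_thresholds(scores)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  # midpoint thresholds never coincide with a score, so counting scores
  # <= t (findInterval on the sorted class scores) counts scores < t
  pos_sorted <- sort(scores[labels == 1])
  neg_sorted <- sort(scores[labels == 0])
  se <- (n_pos - findInterval(thresholds, pos_sorted)) / n_pos
  sp <- findInterval(thresholds, neg_sorted) / n_neg
  structure(data.frame(threshold = thresholds, sensitivity = se,
                       specificity = sp),
            class = c("roc_curve", "data.frame"))
}

candidate_thresholds <- function(scores) {
  u <- sort(unique(scores))
  mids <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else numeric(0)
  c(-Inf, mids, Inf)
}

check_binary <- function(labels, scores) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores), all(labels %in% c(0L, 1L)))
  if (length(unique(labels)) < 2) stop("both classes must be present")
  labels
}

#' Area under the ROC curve
#'
#' Mann-Whitney estimator: the fraction of (positive, negative) score pairs
#' that are concordant, counting ties as one half. Equals the trapezoidal
#' area under the step ROC curve and is invariant to strictly monotone
#' transforms of the scores.
#'
#' @inheritParams roc_points
#' @return AUC in [0, 1].
#' @export
auc_score <- function(scores, labels) {
  labels <- check_binary(labels, scores)
  r <- rank(scores)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Optimal ROC cutoff by the closest-to-(0,1) criterion
#'
#' Returns the threshold minimizing the Euclidean distance
#' `sqrt((1 - Se)^2 + (1 - Sp)^2)` to the perfect-classifier corner of ROC
#' space (used here instead of the Youden index). Ties are broken by larger
#' sensitivity, then by the smallest threshold.
#'
#' @param curve A `roc_curve` from [roc_points()].
#' @return The selected threshold.
#' @export
cutoff_closest_to_01 <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"), nrow(curve) >= 1)
  d2 <- (1 - curve$sensitivity)^2 + (1 - curve$specificity)^2
  best <- which(d2 == min(d2))
  if (length(best) > 1) {
    best <- best[curve$sensitivity[best] == max(curve$sensitivity[best])]
  }
  min(curve$threshold[best])
}

#' Sensitivity/specificity-balanced threshold
#'
#' Over the candidate thresholds (score midpoints plus sentinels), returns
#' the one minimizing `|Se - Sp|` on the given set; ties are broken by
#' maximal `Se + Sp`, then by the smallest threshold. This is the per-fold
#' training-set threshold used to turn model probabilities into crisp
#' labels.
#'
#' @inheritParams roc_points
#' @return The selected threshold (possibly a `+/-Inf` sentinel when all
#'   scores are equal).
#' @export
balance_threshold <- function(scores, labels) {
  curve <- roc_points(scores, labels)
  gap <- abs(curve$sensitivity - curve$specificity)
  best <- which(gap == min(gap))
  if (length(best) > 1) {
    tot <- curve$sensitivity[best] + curve$specificity[best]
    best <- best[tot == max(tot)]
  }
  min(curve$threshold[best])
}
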