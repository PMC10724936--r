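#' Confusion matrix from binary predictions
#'
#' @param predictions,truth Binary 0/1 vectors of equal length.
#' @return Object of class `confusion_matrix` with counts `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
confusion_matrix <- function(predictions, truth) {
  predictions <- as.integer(predictions)
  truth <- as.integer(truth)
  stopifnot(length(predictions) == length(truth),
            all(predictions %in% c(0L, 1L)), all(truth %in% c(0L, 1L)))
  structure(list(
    tp = sum(predictions == 1 & truth == 1),
    tn = sum(predictions == 0 & truth == 0),
    fp = sum(predictions == 1 & truth == 0),
    fn = sum(predictions == 0 & truth == 1)
  ), class = "confusion_matrix")
}

#' Diagnostic metrics from a confusion matrix
#'
#' Accuracy `(TP + TN) / (TP + TN + FP + FN)`, sensitivity `TP / (TP + FN)`,
#' specificity `TN / (TN + FP)`, PPV `TP / (TP + FP)` and NPV
#' `TN / (TN + FN)`, all in percent. A metric whose denominator is zero is
#' reported as `NA` (undefined), never as a propagated NaN.
#'
#' @param cm A [confusion_matrix()] or list with `tp`, `tn`, `fp`, `fn`.
#' @return Named numeric vector `accuracy`, `sensitivity`, `specificity`,
#'   `ppv`, `npv` (percent; `NA` = undefined).
#' @export
diagnostic_metrics <- function(cm) {
  with(cm, {
    stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0, tp + tn + fp + fn > 0)
    safe <- function(num, den) if (den > 0) 100 * num / den else NA_real_
    c(accuracy = 100 * (tp + tn) / (tp + tn + fp + fn),
      sensitivity = safe(tp, tp + fn),
      specificity = safe(tn, tn + fp),
      ppv = safe(tp, tp + fp),
      npv = safe(tn, tn + fn))
  })
}

#' Wilson score interval for a binomial proportion
#'
#' The 95% interval uses the conventional z = 1.96 (other levels use the
#' exact normal quantile). Returned in percent. The Wilson interval never
#' attains 0 or 100 for 0 < n < Inf.
#'
#' @param successes,n Counts, `0 <= successes <= n`, `n > 0`.
#' @param level Confidence level (default 0.95).
#' @return `c(low, high)` in percent.
#' @export
wilson_ci <- function(successes, n, level = 0.95) {
  stopifnot(n > 0, successes >= 0, successes <= n)
  z <- if (identical(level, 0.95)) 1.96 else qnorm(1 - (1 - level) / 2)
  p <- successes / n
  den <- 1 + z^2 / n
  center <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  100 * c((center - half) / den, (center + half) / den)
}

#' Hanley-McNeil confidence interval for an AUC
#'
#' Closed-form standard error
#' `SE^2 = [A(1-A) + (n_pos-1)(Q1 - A^2) + (n_neg-1)(Q2 - A^2)] /
#' (n_pos n_neg)` with `Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`; the interval is
#' `A +/- z SE`, clamped to [0, 1]. Intended for `A >= 0.5` (the usual
#' orientation).
#'
#' @param auc Estimated AUC.
#' @param n_pos,n_neg Class sizes, both >= 2.
#' @param level Confidence level.
#' @return `c(low, high)`.
#' @export
auc_ci_hanley_mcneil <- function(auc, n_pos, n_neg, level = 0.95) {
  stopifnot(auc >= 0, auc <= 1, n_pos >= 2, n_neg >= 2)
  z <- if (identical(level, 0.95)) 1.96 else qnorm(1 - (1 - level) / 2)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  c(max(auc - z * se, 0), min(auc + z * se, 1))
}

#' Subgroup diagnostic breakdown
#'
#' Accuracy of a prediction vector inside vs outside a configurable FFR
#' gray zone (default the narrower decision zone [0.75, 0.83]) and per
#' category of vessel, proximal-LAD flag, sex, hypertension and diabetes.
#' Empty subgroups are reported with `n = 0` and `NA` accuracy.
#'
#' @param predictions,labels Binary 0/1 vectors.
#' @param metadata Data frame with one row per lesion: `corrected_ffr`,
#'   `vessel`, `proximal_lad`, `sex`, `aht`, `diabetes`.
#' @param gray_zone `c(lo, hi)` FFR bounds of the zone split.
#' @return Data frame `group`, `category`, `n`, `correct`, `accuracy`
#'   (percent).
#' @export
subgroup_report <- function(predictions, labels, metadata,
                            gray_zone = c(0.75, 0.83)) {
  predictions <- as.integer(predictions)
  labels <- as.integer(labels)
  stopifnot(nrow(metadata) == length(labels))
  correct <- predictions == labels
  in_zone <- metadata$corrected_ffr >= gray_zone[1] &
    metadata$corrected_ffr <= gray_zone[2]
  groups <- list(
    ffr_zone = ifelse(in_zone, "inside_gray_zone", "outside_gray_zone"),
    vessel = as.character(metadata$vessel),
    proximal_lad = ifelse(metadata$proximal_lad == 1, "yes", "no"),
    sex = as.character(metadata$sex),
    aht = ifelse(metadata$aht == 1, "yes", "no"),
    diabetes = ifelse(metadata$diabetes == 1, "yes", "no")
  )
  rows <- list()
  for (g in names(groups)) {
    for (cat in sort(unique(groups[[g]]))) {
      sel <- groups[[g]] == cat
      n <- sum(sel)
      rows[[length(rows) + 1]] <- data.frame(
        group = g, category = cat, n = n, correct = sum(correct[sel]),
        accuracy = if (n > 0) 100 * mean(correct[sel]) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Multivariate baseline under the same validation protocol
#'
#' Fits one multivariate model (default a 100-tree random forest) on the
#' top-k ranked features under the same leave-one-patient-out protocol as
#' the univariate models, for each k in `ks`, reporting accuracy with a
#' Wilson 95% CI for comparison with the voting ensemble.
#'
#' @param x Feature matrix (columns named).
#' @param y Binary labels.
#' @param patients Patient id per lesion.
#' @param ranked_features Features in rank order.
#' @param ks Ensemble sizes to evaluate (default 5:13).
#' @param algorithm Learner id (default `"rf100"`).
#' @param seed Fold-fit seed.
#' @return Data frame `k`, `accuracy`, `ci_low`, `ci_high` (percent).
#' @export
multivariate_baseline <- function(x, y, patients, ranked_features,
                                  ks = 5:13, algorithm = "rf100",
                                  seed = 0L) {
  stopifnot(max(ks) <= length(ranked_features))
  rows <- lapply(ks, function(k) {
    out <- lopo_univariate_predictions(
      x[, ranked_features[seq_len(k)], drop = FALSE], y, patients,
      algorithm = algorithm, feature_name = paste0("top", k), seed = seed)
    ok <- !is.na(out$crisp)
    ci <- wilson_ci(sum(out$crisp[ok] == y[ok]), sum(ok))
    data.frame(k = k, accuracy = 100 * out$accuracy,
               ci_low = ci[1], ci_high = ci[2])
  })
  do.call(rbind, rows)
}
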