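#' Log-odds voting weight from a model's accuracy
#'
#' `w = log(acc / (1 - acc))` (natural log; because the weighted vote is
#' normalized before thresholding, the log base cancels and is immaterial).
#' Accuracies are clipped to `[epsilon, 1 - epsilon]` so the weight stays
#' finite at 0 and 1; models below chance get a negative weight.
#'
#' @param acc Accuracy fraction(s) in (0, 1) (clipped first).
#' @param epsilon Clipping bound in (0, 0.5).
#' @return Numeric weight(s).
#' @export
weight_from_accuracy <- function(acc, epsilon = 1e-6) {
  stopifnot(epsilon > 0, epsilon < 0.5)
  a <- pmin(pmax(acc, epsilon), 1 - epsilon)
  log(a / (1 - a))
}

#' Per-model binary votes under the M1/M2/M3 aggregation strategies
#'
#' Turns the out-of-fold outputs of the univariate models into one binary
#' vote per model and lesion:
#' * **M1** — each model's probability ROC yields a closest-to-(0,1)
#'   cutoff; the *mean* cutoff over models thresholds every model's
#'   probabilities.
#' * **M2** — each model's probabilities are thresholded at its *own* ROC
#'   cutoff.
#' * **M3** — the votes are the models' crisp labels (already thresholded
#'   per fold); the ROC cutoff of the mean crisp vote is computed and
#'   reported alongside (it is degenerate by construction, votes are not
#'   re-thresholded with it).
#'
#' @param outputs List of `model_output` (same lesion set, same order).
#' @param labels Binary labels used for the ROC analyses.
#' @param strategy `"M1"`, `"M2"` or `"M3"`.
#' @return List with `votes` (lesions x models 0/1 matrix), `cutoffs`
#'   (per-model ROC cutoffs), `mean_cutoff`.
#' @export
make_votes <- function(outputs, labels, strategy = c("M1", "M2", "M3")) {
  strategy <- match.arg(strategy)
  stopifnot(length(outputs) >= 1)
  ids <- lapply(outputs, `[[`, "lesion_id")
  if (!all(vapply(ids, identical, logical(1), ids[[1]]))) {
    stop("model outputs cover different lesion sets")
  }
  probs <- vapply(outputs, `[[`, numeric(length(labels)), "prob")
  crisp <- vapply(outputs, `[[`, numeric(length(labels)), "crisp")
  if (strategy == "M3") {
    mean_vote <- rowMeans(crisp)
    cut <- cutoff_closest_to_01(roc_points(mean_vote, labels))
    return(list(votes = crisp, cutoffs = rep(NA_real_, ncol(crisp)),
                mean_cutoff = cut))
  }
  cutoffs <- apply(probs, 2, function(p)
    cutoff_closest_to_01(roc_points(p, labels)))
  if (strategy == "M1") {
    tau <- mean(cutoffs)
    votes <- (probs >= tau) * 1
  } else {
    tau <- NA_real_
    votes <- sweep(probs, 2, cutoffs, ">=") * 1
  }
  list(votes = votes, cutoffs = cutoffs, mean_cutoff = tau)
}

#' Aggregate model votes into an ensemble prediction
#'
#' Simple majority: the ensemble score is the mean vote. Weighted voting:
#' the score is the weight-normalized sum `sum(w_i v_i) / sum(w_i)` with
#' log-odds weights from each model's accuracy (normalization makes the
#' 0.5 comparison invariant to rescaling all weights). The final label is
#' `score >= 0.5`; a tie at exactly 0.5 errs toward the positive
#' (significant-lesion) class.
#'
#' @param votes Lesions x models 0/1 matrix (from [make_votes()]).
#' @param voting `"simple"` or `"weighted"`.
#' @param accuracies Per-model accuracy fractions (required for weighted).
#' @param epsilon Clipping bound passed to [weight_from_accuracy()].
#' @return Object of class `ensemble_prediction`: `score`, `label`,
#'   `weights`, `votes`, `voting`.
#' @export
aggregate_votes <- function(votes, voting = c("simple", "weighted"),
                            accuracies = NULL, epsilon = 1e-6) {
  voting <- match.arg(voting)
  votes <- as.matrix(votes)
  stopifnot(all(votes %in% c(0, 1)))
  if (voting == "simple") {
    w <- rep(1, ncol(votes))
    score <- rowMeans(votes)
  } else {
    stopifnot(!is.null(accuracies), length(accuracies) == ncol(votes))
    w <- weight_from_accuracy(accuracies, epsilon)
    if (sum(w) <= 0) {
      stop("non-positive total weight (all models at or below chance); ",
           "use simple voting")
    }
    score <- as.numeric(votes %*% w) / sum(w)
  }
  structure(list(score = score, label = as.integer(score >= 0.5),
                 weights = w, votes = votes, voting = voting),
            class = "ensemble_prediction")
}

#' Top-k ensemble sweep
#'
#' For each k up to `k_max` and each aggregation strategy, builds the
#' ensemble of the first k ranked univariate models, aggregates the votes,
#' and evaluates against the labels: accuracy with a Wilson 95% CI, plus
#' AUCs of the mean crisp vote and the mean class probability with
#' Hanley-McNeil 95% CIs.
#'
#' @param outputs List of `model_output` in rank order (rank 1 first).
#' @param labels Binary labels.
#' @param k_max Largest ensemble size (default all models).
#' @param strategies Subset of `c("M1", "M2", "M3")`.
#' @param voting `"simple"` or `"weighted"`.
#' @param level CI level.
#' @return Data frame: one row per (strategy, k) with `accuracy`, `ci_low`,
#'   `ci_high`, `auc_crisp`, `auc_crisp_low/high`, `auc_prob`,
#'   `auc_prob_low/high` (accuracy in percent, AUC as fractions).
#' @export
run_topk_sweep <- function(outputs, labels, k_max = length(outputs),
                           strategies = c("M1", "M2", "M3"),
                           voting = "weighted", level = 0.95) {
  stopifnot(k_max >= 1, k_max <= length(outputs))
  labels <- as.integer(labels)
  n <- length(labels)
  n_pos <- sum(labels == 1)
  n_neg <- n - n_pos
  rows <- list()
  for (strategy in strategies) {
    for (k in seq_len(k_max)) {
      sub <- outputs[seq_len(k)]
      mv <- make_votes(sub, labels, strategy)
      acc_i <- vapply(sub, `[[`, numeric(1), "accuracy")
      pred <- aggregate_votes(mv$votes, voting, accuracies = acc_i)
      correct <- sum(pred$label == labels)
      ci <- wilson_ci(correct, n, level)
      mean_crisp <- rowMeans(vapply(sub, `[[`, numeric(n), "crisp"))
      mean_prob <- rowMeans(vapply(sub, `[[`, numeric(n), "prob"))
      auc_c <- auc_score(mean_crisp, labels)
      auc_p <- auc_score(mean_prob, labels)
      ci_c <- auc_ci_hanley_mcneil(auc_c, n_pos, n_neg, level)
      ci_p <- auc_ci_hanley_mcneil(auc_p, n_pos, n_neg, level)
      rows[[length(rows) + 1]] <- data.frame(
        strategy = strategy, voting = voting, k = k,
        accuracy = 100 * correct / n, ci_low = ci[1], ci_high = ci[2],
        auc_crisp = auc_c, auc_crisp_low = ci_c[1], auc_crisp_high = ci_c[2],
        auc_prob = auc_p, auc_prob_low = ci_p[1], auc_prob_high = ci_p[2],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
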