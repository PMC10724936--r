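# Grouped (patient-level) cross-validation and the univariate model study.

# assign patients to n_folds folds, stratified by the patient-level label
# (majority label of the patient's lesions, ties -> positive)
make_group_folds <- function(patients, labels, n_folds, seed = 0L) {
  set.seed(seed)
  ids <- unique(patients)
  plab <- vapply(ids, function(p) {
    as.integer(mean(labels[patients == p]) >= 0.5)
  }, integer(1))
  fold_of <- setNames(integer(length(ids)), ids)
  for (cls in unique(plab)) {
    members <- sample(ids[plab == cls])
    fold_of[members] <- (seq_along(members) - 1L) %% n_folds + 1L
  }
  fold_of[patients]
}

#' Tenfold accuracy study for one univariate model
#'
#' For each seed, runs stratified patient-grouped k-fold cross-validation of
#' one learner on one feature: per fold, the learner is fit on the training
#' patients, a threshold balancing sensitivity and specificity is chosen on
#' the training scores, and held-out lesions are classified with it. The
#' per-seed pooled accuracies are summarized by mean/sd/max/min (percent),
#' the shape of the published per-feature accuracy table.
#'
#' @param x Numeric matrix with the feature column(s) used by the model.
#' @param y Binary labels (0/1).
#' @param patients Patient id per lesion (grouping unit).
#' @param algorithm Learner id from [learner_registry()].
#' @param feature_name Label carried into the summary.
#' @param seeds Integer seeds (default 0:9, i.e. 10 seeds).
#' @param n_folds Number of folds (default 10).
#' @return Object of class `accuracy_summary` with fields `feature`,
#'   `algorithm`, `per_seed` (named percent accuracies), `mean`, `sd`,
#'   `max`, `min`.
#' @export
tenfold_accuracy_study <- function(x, y, patients, algorithm,
                                   feature_name = colnames(x)[1],
                                   seeds = 0:9, n_folds = 10L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("labels are single-class")
  if (length(unique(patients)) < n_folds) {
    stop("need at least ", n_folds, " patients for ", n_folds, "-fold CV")
  }
  acc <- vapply(seeds, function(s) {
    folds <- make_group_folds(patients, y, n_folds, seed = s)
    pred <- rep(NA_integer_, length(y))
    for (f in sort(unique(folds))) {
      test <- folds == f
      if (length(unique(y[!test])) < 2) next
      model <- fit_learner(algorithm, x[!test, , drop = FALSE], y[!test],
                           seed = s)
      train_scores <- predict_prob(model, x[!test, , drop = FALSE])
      thr <- balance_threshold(train_scores, y[!test])
      pred[test] <- as.integer(predict_prob(model, x[test, , drop = FALSE]) >= thr)
    }
    100 * mean(pred == y, na.rm = TRUE)
  }, numeric(1))
  names(acc) <- paste0("seed", seeds)
  structure(list(feature = feature_name, algorithm = algorithm,
                 per_seed = acc, mean = mean(acc), sd = sd(acc),
                 max = max(acc), min = min(acc)),
            class = "accuracy_summary")
}

#' @export
print.accuracy_summary <- function(x, ...) {
  cat(sprintf("<accuracy_summary %s / %s: mean %.2f%% sd %.2f max %.2f min %.2f>\n",
              x$feature, x$algorithm, x$mean, x$sd, x$max, x$min))
  invisible(x)
}

#' Pick the best learner for a feature
#'
#' Argmax of mean accuracy over the supplied summaries; ties are broken by
#' lower standard deviation, then by registry order.
#'
#' @param summaries List of `accuracy_summary` for one feature.
#' @return The winning `accuracy_summary`.
#' @export
select_best_algorithm <- function(summaries) {
  stopifnot(length(summaries) >= 1)
  means <- vapply(summaries, `[[`, numeric(1), "mean")
  sds <- vapply(summaries, `[[`, numeric(1), "sd")
  reg <- match(vapply(summaries, `[[`, character(1), "algorithm"),
               learner_registry()$id)
  best <- order(-means, sds, reg)[1]
  summaries[[best]]
}

#' Feature ranking by mean univariate accuracy
#'
#' Keeps features whose mean accuracy is at least `min_mean_acc` percent
#' (the rule that selects the published top-14 set) and orders them either
#' as given (the published-table order, used on real data) or by descending
#' mean accuracy (used on synthetic data).
#'
#' @param accuracies Data frame with columns `feature` and `mean_acc`
#'   (percent), or a list of `accuracy_summary`.
#' @param min_mean_acc Cutoff in percent (default 60).
#' @param order `"given"` or `"mean"`.
#' @return Character vector of kept features (possibly empty).
#' @export
rank_features <- function(accuracies, min_mean_acc = 60,
                          order = c("given", "mean")) {
  order <- match.arg(order)
  if (!is.data.frame(accuracies)) {
    accuracies <- data.frame(
      feature = vapply(accuracies, `[[`, character(1), "feature"),
      mean_acc = vapply(accuracies, `[[`, numeric(1), "mean"),
      stringsAsFactors = FALSE)
  }
  kept <- accuracies[accuracies$mean_acc >= min_mean_acc, ]
  if (order == "mean") kept <- kept[base::order(-kept$mean_acc), ]
  kept$feature
}

#' Leave-one-patient-out predictions for one model
#'
#' One fold per patient: the model is fit on all other patients' lesions, a
#' sensitivity/specificity-balanced threshold is chosen on the training
#' scores, and the held-out lesions receive an out-of-fold class
#' probability `O_i` and crisp label `C_i = (O_i >= threshold)`. A fold
#' whose training labels are single-class is skipped with a warning (its
#' lesions get NA). The pooled out-of-fold accuracy `acc` feeds the
#' log-odds voting weights.
#'
#' @param x Numeric feature matrix (one column for a univariate model; the
#'   multivariate baseline passes several).
#' @param y Binary labels (0/1).
#' @param patients Patient id per lesion.
#' @param algorithm Learner id from [learner_registry()].
#' @param feature_name Label carried into the output.
#' @param seed Seed applied to every fold's fit.
#' @return Object of class `model_output`: `lesion_id`, `prob`, `crisp`,
#'   `accuracy` (fraction), `feature`, `algorithm`, `n_folds`.
#' @export
lopo_univariate_predictions <- function(x, y, patients,
                                        algorithm = "logistic",
                                        feature_name = colnames(x)[1],
                                        seed = 0L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  ids <- unique(patients)
  if (length(ids) < 2) stop("need at least 2 patients")
  prob <- rep(NA_real_, length(y))
  crisp <- rep(NA_integer_, length(y))
  for (p in ids) {
    test <- patients == p
    if (length(unique(y[!test])) < 2) {
      warning("fold for patient ", p, " skipped: single-class training labels")
      next
    }
    model <- fit_learner(algorithm, x[!test, , drop = FALSE], y[!test],
                         seed = seed)
    thr <- balance_threshold(predict_prob(model, x[!test, , drop = FALSE]),
                             y[!test])
    prob[test] <- predict_prob(model, x[test, , drop = FALSE])
    crisp[test] <- as.integer(prob[test] >= thr)
  }
  structure(list(
    lesion_id = if (!is.null(rownames(x))) rownames(x) else seq_along(y),
    prob = prob, crisp = crisp,
    accuracy = mean(crisp == y, na.rm = TRUE),
    feature = feature_name, algorithm = algorithm,
    n_folds = length(ids)
  ), class = "model_output")
}

#' @export
print.model_output <- function(x, ...) {
  cat(sprintf("<model_output %s / %s: %d folds, out-of-fold accuracy %.2f%%>\n",
              x$feature, x$algorithm, x$n_folds, 100 * x$accuracy))
  invisible(x)
}
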