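#!/usr/bin/env Rscript
# Stage 4: leave-one-patient-out ensembles.
#
# Refits each ranked feature's best learner under leave-one-patient-out
# (80 folds, per-fold balanced thresholds), then sweeps ensembles of the
# top-k models for k = 1..K under the three vote-construction strategies
# (M1 mean ROC cutoff on probabilities, M2 per-model cutoffs, M3 crisp
# labels) with weighted and simple voting. Writes univariate_outputs.csv
# and ensemble_report.csv.

suppressMessages(library(octffr))

cohort <- read_cohort("results/cohort")
labels <- read.csv("results/labels.csv")
features <- read.csv("results/features.csv")
accs <- read.csv("results/univariate_accuracies.csv")
ranked <- read.csv("results/ranked_features.csv")$feature

fm <- as.matrix(features[, -1])
y <- labels$label
patients <- cohort$lesions$patient_id

outs <- lapply(ranked, function(f) {
  alg <- accs$algorithm[accs$feature == f]
  lopo_univariate_predictions(fm[, f, drop = FALSE], y, patients, alg,
                              feature_name = f, seed = 0)
})
cat("out-of-fold univariate accuracies:\n")
for (o in outs) {
  cat(sprintf("  %-30s %-12s %.2f%%\n", o$feature, o$algorithm,
              100 * o$accuracy))
}
long <- do.call(rbind, lapply(outs, function(o) {
  data.frame(lesion_id = o$lesion_id, feature = o$feature,
             algorithm = o$algorithm, prob = o$prob, crisp = o$crisp)
}))
write.csv(long, "results/univariate_outputs.csv", row.names = FALSE,
          quote = FALSE)

k_max <- min(13L, length(outs))
report <- rbind(
  run_topk_sweep(outs, y, k_max = k_max, voting = "weighted"),
  run_topk_sweep(outs, y, k_max = k_max, voting = "simple"))
write.csv(report, "results/ensemble_report.csv", row.names = FALSE,
          quote = FALSE)

best <- report[which.max(report$accuracy), ]
cat(sprintf("\nbest ensemble: %s voting, strategy %s, k = %d -> %.2f%% (%.2f, %.2f)\n",
            best$voting, best$strategy, best$k, best$accuracy,
            best$ci_low, best$ci_high))
cat(sprintf("AUC (crisp votes) %.3f (%.3f, %.3f); AUC (mean probability) %.3f\n",
            best$auc_crisp, best$auc_crisp_low, best$auc_crisp_high,
            best$auc_prob))
cat(sprintf("mean univariate accuracy: %.2f%%\n",
            100 * mean(vapply(outs, `[[`, numeric(1), "accuracy"))))
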