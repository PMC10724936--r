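#!/usr/bin/env Rscript
# Stage 5: diagnostic report for the best ensemble.
#
# Rebuilds the best ensemble found in stage 4, reports the confusion
# matrix with accuracy/Se/Sp/PPV/NPV and Wilson 95% CIs, the AUCs with
# Hanley-McNeil CIs, the gray-zone split ([0.75, 0.83]) and clinical
# subgroup accuracies, and a multivariate random-forest baseline on the
# top-k features under the same leave-one-patient-out protocol.

suppressMessages(library(octffr))

cohort <- read_cohort("results/cohort")
labels <- read.csv("results/labels.csv")
features <- read.csv("results/features.csv")
outputs <- read.csv("results/univariate_outputs.csv")
ranked <- read.csv("results/ranked_features.csv")$feature
report <- read.csv("results/ensemble_report.csv")

y <- labels$label
fm <- as.matrix(features[, -1])
patients <- cohort$lesions$patient_id

outs <- lapply(ranked, function(f) {
  sub <- outputs[outputs$feature == f, ]
  structure(list(lesion_id = sub$lesion_id, prob = sub$prob,
                 crisp = sub$crisp, accuracy = mean(sub$crisp == y),
                 feature = f, algorithm = sub$algorithm[1],
                 n_folds = length(unique(patients))),
            class = "model_output")
})

best <- report[which.max(report$accuracy), ]
cat(sprintf("best ensemble: %s / %s voting, k = %d\n",
            best$strategy, best$voting, best$k))
sub <- outs[seq_len(best$k)]
mv <- make_votes(sub, y, best$strategy)
pred <- aggregate_votes(mv$votes, best$voting,
                        vapply(sub, `[[`, numeric(1), "accuracy"))

cm <- confusion_matrix(pred$label, y)
metrics <- diagnostic_metrics(cm)
cat(sprintf("confusion: TP %d TN %d FP %d FN %d\n", cm$tp, cm$tn, cm$fp, cm$fn))
ci_n <- list(accuracy = c(cm$tp + cm$tn, length(y)),
             sensitivity = c(cm$tp, cm$tp + cm$fn),
             specificity = c(cm$tn, cm$tn + cm$fp),
             ppv = c(cm$tp, cm$tp + cm$fp),
             npv = c(cm$tn, cm$tn + cm$fn))
metric_rows <- lapply(names(ci_n), function(m) {
  ci <- wilson_ci(ci_n[[m]][1], ci_n[[m]][2])
  cat(sprintf("%-12s %6.2f%% (%.2f, %.2f)\n", m, metrics[[m]], ci[1], ci[2]))
  data.frame(metric = m, value = metrics[[m]], ci_low = ci[1], ci_high = ci[2])
})

meta <- cohort$lesions
meta$sex <- cohort$patients$sex[match(meta$patient_id,
                                      cohort$patients$patient_id)]
meta$aht <- cohort$patients$aht[match(meta$patient_id,
                                      cohort$patients$patient_id)]
meta$diabetes <- cohort$patients$diabetes[match(meta$patient_id,
                                                cohort$patients$patient_id)]
meta$corrected_ffr <- labels$corrected_ffr
groups <- subgroup_report(pred$label, y, meta, gray_zone = c(0.75, 0.83))
cat("\nsubgroup accuracies:\n")
print(groups, row.names = FALSE)

cat("\nmultivariate random-forest baseline (top 5..13 features, LOPO):\n")
ks <- 5:min(13, length(ranked))
baseline <- multivariate_baseline(fm, y, patients, ranked, ks = ks,
                                  algorithm = "rf100", seed = 0)
print(baseline, row.names = FALSE)
cat(sprintf("best baseline: k = %d -> %.2f%%; best ensemble: %.2f%%\n",
            baseline$k[which.max(baseline$accuracy)], max(baseline$accuracy),
            best$accuracy))

write.csv(do.call(rbind, metric_rows), "results/report_metrics.csv",
          row.names = FALSE, quote = FALSE)
write.csv(groups, "results/report_subgroups.csv", row.names = FALSE,
          quote = FALSE)
write.csv(baseline, "results/report_baseline.csv", row.names = FALSE,
          quote = FALSE)
jsonlite::write_json(
  list(strategy = best$strategy, voting = best$voting, k = best$k,
       confusion = list(tp = cm$tp, tn = cm$tn, fp = cm$fp, fn = cm$fn),
       metrics = as.list(metrics),
       auc_crisp = best$auc_crisp, auc_prob = best$auc_prob),
  "results/report.json", auto_unbox = TRUE, digits = NA)
cat("\nwrote results/report_{metrics,subgroups,baseline}.csv and report.json\n")
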