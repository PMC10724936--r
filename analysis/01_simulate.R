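#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Generates the default synthetic cohort (80 patients, 102 intermediate
# lesions, FFR calibrated to mean 0.80 / sd 0.08 with 25/47/30 zone masses,
# drift of 2 mmHg in 12 lesions and 3 mmHg in 3) and writes it as
# delimited text under results/cohort/, plus the drift-corrected labels.

suppressMessages(library(octffr))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L

cfg <- cohort_config(seed = seed)
cohort <- generate_cohort(cfg)
write_cohort(cohort, "results/cohort")

labels <- label_cohort(cohort$lesions)
write.csv(labels, "results/labels.csv", row.names = FALSE, quote = FALSE)

cat(sprintf("cohort: %d patients, %d lesions (seed %d)\n",
            nrow(cohort$patients), nrow(cohort$lesions), seed))
cat(sprintf("vessels: %s\n",
            paste(names(table(cohort$lesions$vessel)),
                  table(cohort$lesions$vessel), sep = "=", collapse = " ")))
cat(sprintf("corrected FFR: mean %.3f, sd %.3f\n",
            mean(labels$corrected_ffr), sd(labels$corrected_ffr)))
cat(sprintf("zones: %s\n",
            paste(names(table(labels$zone)), table(labels$zone),
                  sep = "=", collapse = " ")))
cat(sprintf("significant (FFR <= 0.80): %d / %d\n",
            sum(labels$label), nrow(labels)))
cat(sprintf("drift-adjusted lesions: %d (D=2: %d, D=3: %d)\n",
            sum(labels$adjusted), sum(cohort$lesions$drift == 2),
            sum(cohort$lesions$drift == 3)))
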