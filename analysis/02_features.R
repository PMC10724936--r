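#!/usr/bin/env Rscript
# Stage 2: extract the 26-feature matrix.
#
# Reads the simulated cohort, computes the 12 geometric features from each
# lumen profile, joins the physician MLD and the 13 clinical covariates,
# L1-normalizes per column, prunes perfectly correlated features
# (|r| >= 0.999) and writes features.csv + correlation.csv.

suppressMessages(library(octffr))

cohort <- read_cohort("results/cohort")
fm <- assemble_feature_matrix(cohort)
fm_norm <- l1_normalize(fm)

cc <- pearson_correlation_matrix(fm_norm)
write.csv(round(cc, 6), "results/correlation.csv")

pruned <- prune_perfectly_correlated(fm_norm)
write.csv(data.frame(lesion_id = rownames(fm_norm), fm_norm),
          "results/features.csv", row.names = FALSE, quote = FALSE)

cat(sprintf("feature matrix: %d lesions x %d features (L1-normalized)\n",
            nrow(fm_norm), ncol(fm_norm)))
hi <- which(abs(cc) > 0.95 & upper.tri(cc), arr.ind = TRUE)
if (nrow(hi)) {
  cat("strongly correlated pairs (|r| > 0.95):\n")
  for (i in seq_len(nrow(hi))) {
    cat(sprintf("  %s ~ %s: r = %.3f\n", rownames(cc)[hi[i, 1]],
                colnames(cc)[hi[i, 2]], cc[hi[i, 1], hi[i, 2]]))
  }
}
cat(sprintf("pruned at |r| >= 0.999: %s\n",
            if (length(pruned$removed)) paste(pruned$removed, collapse = ", ")
            else "none (raised-cosine stenoses keep the rapport pair distinct)"))
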