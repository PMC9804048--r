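#!/usr/bin/env Rscript
# Group statistics on the temporal metrics: LID vs NoLID within each phase
# (Mann-Whitney via the normality gate), OFF vs ON within each group
# (Wilcoxon signed-rank), and AIMS severity correlations in the LID ON phase
# (partial Spearman adjusting for age at onset, LEDD and disease duration,
# FDR-corrected across states).

library(dfncstates)

coh <- read_cohort("results/cohort")
metrics <- read.table("results/temporal_metrics.tsv", sep = "\t",
                      header = TRUE, stringsAsFactors = FALSE)
res <- run_full_comparison(metrics, coh$subjects)
write.table(res$comparisons, "results/comparisons.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(res$correlations, "results/correlations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("contrasts with p < 0.05:\n")
sig <- subset(res$comparisons, !is.na(p_value) & p_value < 0.05)
print(sig[, c("metric", "state", "contrast", "test", "p_value")],
      row.names = FALSE)
cat("\nseverity correlations (FDR within metric across states):\n")
print(res$correlations[, c("metric", "state", "rho", "p_value", "p_adjusted",
                           "significant")], row.names = FALSE)

# demographic worked example: gender split of the two groups
chi <- chi_square_counts(rbind(c(22, 19), c(21, 13)))
cat(sprintf("\ngender 2x2 chi-squared (no continuity correction): X2 = %.3f, p = %.3f\n",
            chi$statistic, chi$p_value))
cat("written: results/comparisons.tsv, results/correlations.tsv\n")
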