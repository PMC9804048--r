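#!/usr/bin/env Rscript
# Temporal properties of the recovered states: per-session fractional windows
# (occupancy), mean dwell time and number of transitions, plus recovery
# scoring against the generator's hidden state paths.

library(dfncstates)

coh <- read_cohort("results/cohort")
assign <- read.table("results/dfnc/assignments.tsv", sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
k <- max(assign$state)
seqs <- split(assign$state, assign$session)
metrics <- cohort_temporal_metrics(seqs, coh$session_table, k)
write.table(metrics, "results/temporal_metrics.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("per-state occupancy (mean % of windows), by group x phase:\n")
agg <- aggregate(fractional_windows ~ group + phase + state, metrics, mean)
print(reshape(agg, idvar = c("group", "phase"), timevar = "state",
              direction = "wide"), row.names = FALSE)

# recovery against hidden states, windows labelled by majority hidden state
if (!is.null(coh$ground_truth)) {
  maj <- unlist(lapply(names(seqs), function(key)
    majority_states(coh$ground_truth$paths[[key]])))
  rec <- unlist(seqs, use.names = FALSE)
  cat(sprintf("adjusted Rand index vs hidden states: %.3f\n",
              adjusted_rand_index(maj, rec)))
}
cat("written: results/temporal_metrics.tsv\n")
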