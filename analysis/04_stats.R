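#!/usr/bin/env Rscript
# Step 4: pairwise resistance-level comparisons on the cohort metrics.
#
# The test unit is the participant (n = 10 per level), matching how a
# cohort study would compare conditions. Every unordered level pair is
# tested per phase and metric with the two-sided Mann-Whitney U test, raw
# p values flagged at 0.05 (no multiplicity correction).

library(emgsynergy)

metrics <- as.data.frame(data.table::fread("results/cohort_metrics.csv"))
if (nrow(metrics) == 0) stop("run analysis/03_cohort_metrics.R first")

rows <- list()
for (metric in unique(metrics$metric)) {
  for (ph in sort(unique(metrics$phase))) {
    sub <- metrics[metrics$metric == metric & metrics$phase == ph, ]
    res <- pairwise_tests(sub, metric_name = metric)
    res$phase <- ph
    rows[[length(rows) + 1L]] <- res
  }
}
comparisons <- do.call(rbind, rows)
data.table::fwrite(comparisons, "results/cohort_comparisons.csv")

sig <- comparisons[comparisons$significant_at_0_05, ]
cat(sprintf("%d of %d comparisons significant at p < 0.05\n",
            nrow(sig), nrow(comparisons)))
cat("\nsignificant level pairs:\n")
print(sig[, c("metric_name", "phase", "condition_a", "condition_b",
              "U", "p_value")], row.names = FALSE)
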