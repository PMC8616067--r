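#!/usr/bin/env Rscript
# Step 5: figures and summary tables.
#
# Produces one figure per resistance level for the single-participant
# analysis (max-normalized temporal activations beside muscle-weight
# bars) plus contribution and stability summaries, and a cohort-level
# summary of the metric medians by level.

library(emgsynergy)

if (!file.exists("results/single/synergy_W.csv")) {
  stop("run analysis/02_analyze_single.R first")
}
files <- report_experiment("results/single", "results/figures")
cat("wrote:\n")
cat(paste(" ", files, collapse = "\n"), "\n")

if (file.exists("results/cohort_metrics.csv")) {
  metrics <- data.table::fread("results/cohort_metrics.csv")
  med <- stats::aggregate(value ~ metric + phase + condition, metrics, median)
  data.table::fwrite(med, "results/cohort_medians.csv")
  cat("wrote results/cohort_medians.csv\n")
  print(stats::reshape(med[med$metric == "spatial_stability", -1],
                       idvar = "phase", timevar = "condition",
                       direction = "wide"), row.names = FALSE)
}
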