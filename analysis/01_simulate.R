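#!/usr/bin/env Rscript
# Step 1: simulate one participant's recording session to disk.
#
# Mirrors the study protocol: resistance levels 2-5 (level 1 is a
# freewheeling warmup and carries no force demand), 3 trials per level,
# 12 cycles of ~1 s pedaling at 1500 Hz per trial. Raw trials are written
# as CSV (one column per muscle) with YAML metadata and ground-truth
# sidecars plus a checksum manifest. Raw signals are bulky scratch data;
# they go under scratch/, while all derived tables live under results/.

library(emgsynergy)

sim_dir <- "scratch/simdata/P01"
manifest <- simulate_experiment(sim_dir, seed = 20260928L)

cat(sprintf("wrote %d files to %s\n", nrow(manifest), sim_dir))
cat("first entries of the manifest:\n")
print(head(manifest, 6))
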