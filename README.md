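# emgsynergy

Muscle-synergy and inter-cycle stability analysis for surface
electromyography (sEMG) recorded during force-modulated cycling.

When a person pedals at fixed speed against increasing resistance, the
nervous system retunes how activation is distributed across the large leg
muscles — vastus lateralis (VLAT), biceps femoris (BF), tibialis anterior
(TA), gastrocnemius medialis (GAM) — and how reproducible that
distribution is from cycle to cycle. This package implements the full
analysis chain for such recordings, plus a synthetic generator with known
ground truth so every stage is verifiable by parameter recovery:

1. **Linear envelopes** — zero-phase Butterworth high-pass at 10 Hz,
   full-wave rectification, low-pass at 10 Hz, standardization by the
   session-wide median rectified amplitude.
2. **Cycle segmentation** — local minima of the composite (summed)
   envelope, no kinematic input needed.
3. **Time normalization and anchor-based averaging** — cycles resampled
   to a common length; onset/peak/offset anchors aligned by a monotone
   warp before averaging.
4. **Phase decomposition** — non-negative matrix factorization
   `M ≈ W × H` (Lee–Seung multiplicative updates, compiled), with the
   muscle weightings in `W` (m × n) and temporal phase activations in `H`
   (n × t). Order selection takes the smallest n whose variance accounted
   for, `VAF = 1 − ‖M − WH‖²_F / ‖M‖²_F`, reaches 95%; the pedaling cycle
   is decomposed into n = 3 phases (traction, power initiation, power
   end).
5. **Metrics** — relative phase contributions
   `C_i = (Σ_m W_mi)(Σ_t H_i) / Σ_j (Σ_m W_mj)(Σ_t H_j)` and per-phase
   inter-cycle temporal/spatial stability indices (mean pairwise
   correlation of per-cycle `H` rows / `W` columns).
6. **Statistics** — two-sided Mann–Whitney U tests (exact for small
   tie-free samples) across resistance levels 2–5.

See `vignettes/cycling-synergy-methods.Rmd` for the model, all tunable
parameters and the design decisions.

## Worked example

```r
library(emgsynergy)

# one synthetic trial at the default study conditions:
# 4 muscles, 3 planted phases, 12 cycles of ~1 s at 1500 Hz, 30 dB SNR
gen <- generate_trial(synth_config(seed = 1))
env <- preprocess(gen$session)                       # standardized envelopes
b   <- detect_boundaries(composite_envelope(env), 1500)
ncs <- normalize_cycles(segment_cycles(env, b))      # 12 cycles x 4 x 200

M <- do.call(cbind, lapply(1:12, function(k) ncs$tensor[k, , ]))
sel <- select_order(M, vaf_threshold = 0.95, n_max = 4, seed = 1)
sel$order
#> [1] 3
round(sel$vaf_by_order, 4)
#> [1] 0.6448 0.8739 0.9986
```

The 95% VAF criterion picks the three planted phases; one or two
components leave most of the structure unexplained (VAF 0.64 and 0.87).

The `analysis/` directory holds the numbered workflow the package was
built around (run them in order from the repository root):

```sh
Rscript analysis/01_simulate.R        # one participant, levels 2-5 x 3 trials
Rscript analysis/02_analyze_single.R  # full pipeline -> results/single/
Rscript analysis/03_cohort_metrics.R  # 10 participants, in memory
Rscript analysis/04_stats.R           # pairwise level comparisons
Rscript analysis/05_report.R          # figures + summaries
```

Step 2 prints, among other things, the decomposition quality and the mean
phase contributions by resistance level:

```
  condition order       vaf reached
1         2     3 0.9940055    TRUE
2         3     3 0.9968167    TRUE
3         4     3 0.9965933    TRUE
4         5     3 0.9977455    TRUE

  condition   value.1   value.2   value.3
1         2 0.2951800 0.3218390 0.3829810
2         3 0.2934973 0.3317629 0.3747398
3         4 0.2751267 0.3389809 0.3858924
4         5 0.2427379 0.3685495 0.3887126
```

Reading the contribution table: as resistance rises, the traction phase
(phase 1, dominated by TA) loses share while the power-initiation phase
(phase 2, dominated by VLAT) gains — the planted resistance effect
recovered through the complete pipeline. Step 4 then flags the
corresponding level pairs as significant (Mann–Whitney, participant as
unit, n = 10 per level) and shows both stability indices increasing with
resistance level.

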