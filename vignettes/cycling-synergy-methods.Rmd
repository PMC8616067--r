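---
title: "Methods: muscle synergies and inter-cycle stability in force-modulated cycling sEMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: muscle synergies and inter-cycle stability in force-modulated cycling sEMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgsynergy)
```

## The problem

When a person pedals against increasing resistance at a fixed speed, the
nervous system must modulate muscle force in real time. Two observable
signatures of that modulation live in the surface electromyogram (sEMG) of
the large leg muscles: how activation is *distributed* across muscles and
pedaling phases, and how *reproducible* that distribution is from one cycle
to the next. This package implements an analysis pipeline for such
recordings — four muscles (vastus lateralis VLAT, biceps femoris BF,
tibialis anterior TA, gastrocnemius medialis GAM) sampled at 1500 Hz across
stationary-bike resistance levels 2–5 — together with a synthetic generator
that plants known structure so every stage can be verified by parameter
recovery. Because comparable human recordings are not freely available, the
generator is the package's test bed: all quantitative claims in the test
suite are claims about recovery of planted structure, not about human data.

## Pipeline and model

### Linear envelopes

Each channel is high-pass filtered at 10 Hz, full-wave rectified, and
low-pass filtered at 10 Hz. The filter family and order are not dictated by
the processing conventions the pipeline follows, so the package uses the
field-standard choice: a 4th-order Butterworth applied forward–backward
(zero phase), which preserves burst timing. Zero-phase IIR filtering has
edge transients; the implementation pads the series by odd reflection over
eight cutoff periods so transients stay below $10^{-6}$ of the input
magnitude. Negative post-filter overshoot is clipped to zero because the
envelopes feed a nonnegative factorization.

Envelopes are standardized by a single session-wide scalar: the median of
the rectified (pre-smoothing) amplitude pooled over all muscles and trials
of the session. Taking the median before smoothing is a literal reading of
"median rectified amplitude"; the alternative (post-smoothing) is available
by calling `standardize_session()` directly. Standardization preserves
inter-muscle ratios and makes the pipeline invariant to a common gain, so
amplifier settings cancel out.

### Cycle segmentation

Cycles are delimited by local minima of the composite envelope (per-sample
sum over muscles) — a kinematics-free segmentation that exploits the
periodicity of pedaling. Two defaults matter:

* **Minimum boundary separation** — half the cadence inferred from the
  composite autocorrelation. The acf peaks at the period *and its
  multiples*; the implementation takes the smallest-lag peak within 50% of
  the strongest peak, the standard fundamental-vs-harmonic guard in period
  estimation. Taking the globally highest peak instead occasionally locks
  onto twice or three times the period and halves the cycle count.
* **Prominence threshold** — 0.2 of the series range. On burst-like
  envelopes with three activation bursts per cycle, the dips *between*
  bursts reach a prominence of roughly 0.15–0.17 of the range, while
  genuine boundary valleys exceed 0.4. A threshold of 0.1 admits
  inter-burst dips as boundaries whenever jitter displaces a boundary
  valley; 0.2 separates the two populations with a wide margin on both
  sides.

Conflicts within the minimum separation are resolved in favor of the
deeper minimum, then the earlier index. The first and last samples are
admitted as boundaries when the envelope rises away from (falls into) the
edge, so a trial that starts at a cycle boundary is bracketed completely;
partial cycles outside the outermost minima are discarded. All indices are
1-based and cycles are half-open `[start, next_start)` blocks, so
concatenating cycles reproduces the spanned region exactly.

### Time normalization and anchor-based averaging

Cycles of variable native length are resampled to 200 points by linear
interpolation. For averaging, each muscle's activation anchors — onset and
offset (first/last crossing of 20% of the per-cycle maximum, a common sEMG
onset convention) and the peak — are aligned to their median positions
across cycles by a monotone piecewise-linear warp before the pointwise
mean is taken. Out-of-order anchors are dropped per cycle so the warp
never reorders time; muscles that never cross the threshold are averaged
unwarped. The median (not the mean) anchor target resists outlier cycles.
This anchor-warp scheme is this package's declared integration of temporal
and spatial variation prior to averaging; dynamic time warping is out of
scope.

### Phase decomposition

The muscle × time envelope matrix $M$ is factored as $M \approx WH$ with
$W \in \mathbb{R}^{m\times n}_{\ge 0}$ (muscle contributions) and
$H \in \mathbb{R}^{n\times t}_{\ge 0}$ (temporal phase activations), fitted
by Lee–Seung multiplicative updates for the Frobenius loss (implemented in
compiled code; the loss is non-increasing by construction and asserted in
tests). NMF is non-convex, so each fit takes the best of 10 seeded uniform
random initializations scaled to the data mean; convergence is a relative
loss change below $10^{-6}$ or 1000 iterations. Decomposition quality is
the uncentered global variance accounted for,
$\mathrm{VAF} = 1 - \|M - WH\|_F^2 / \|M\|_F^2$, and the order criterion
selects the smallest $n$ whose best-of-restarts VAF reaches 95%. Whether
VAF should be global or per-muscle is an open choice; global VAF is used
throughout, which is the more permissive and more common convention.

The pedaling cycle is decomposed at $n = 3$: one traction phase and two
power-phase components. Condition-level decompositions run on the
*concatenation* of time-normalized cycles rather than on the average
cycle, so per-cycle patterns exist for the stability indices; the average
cycle is available for summary figures. After fitting, each $H$ row is
normalized to unit maximum with the maximum transferred to the matching
$W$ column (the reconstruction is unchanged), and phases are matched
across conditions by greedy correlation assignment on the temporal
patterns, tie-broken by weight-vector correlation. When two models'
temporal patterns live on different time bases the matching falls back to
weight correlations.

### Contribution and stability metrics

The relative contribution of phase $i$ is

$$C_i = \frac{\left(\sum_m W_{mi}\right)\left(\sum_t H_i(t)\right)}
             {\sum_j \left(\sum_m W_{mj}\right)\left(\sum_t H_j(t)\right)},$$

the fraction of total reconstructed amplitude attributable to phase $i$,
with the temporal pattern entering through its time-sum so each $C_i$ is a
scalar on the simplex. The inter-cycle **temporal stability** of a phase
is the mean zero-lag Pearson correlation over all unordered pairs of
per-cycle temporal patterns; **spatial stability** is the same over
per-cycle muscle-weight vectors. Zero-lag correlation (rather than
lag-scanning cross-correlation) is appropriate because cycles are already
time-normalized; pairwise averaging (rather than correlating each cycle to
a template) is the declared reading of a single similarity index over a
set of cycles. Per-cycle patterns come from independent per-cycle NMF fits
matched to the condition-level reference — patterns are *extracted from*
each cycle, not projected — with a fixed-$W$ nonnegative projection
available as `mode = "project"` for users who prefer the constrained
variant. Constant traces make a correlation undefined; such pairs are
skipped, and a phase where every pair is skipped is reported as degenerate
rather than silently imputed.

### Statistics

Metrics are compared across resistance levels with the two-sided
Mann–Whitney U test: exact null enumeration when both samples have at most
20 observations and no ties, otherwise the tie-corrected normal
approximation with continuity correction. The protocol description pairs
observations across levels, but the Mann–Whitney test is unpaired; the
package implements the test as cited, with a Wilcoxon signed-rank variant
behind `method = "signed_rank"` for strictly paired readings. No
multiplicity correction is applied by default (raw $p < 0.05$ convention);
Holm adjustment is available. Which observations form the test unit
(cycles, trials, or participants) is left to the caller: the bundled
workflow uses cycles within a participant for contributions, trials for
stability indices, and participants at the cohort level.

## The synthetic generator

`generate_trial()` builds, per cycle and phase, a truncated-Gaussian
activation bump in normalized cycle time, scaled by a planted weight
matrix and a lognormal amplitude-jitter factor; the summed envelope
amplitude-modulates band-limited (20–450 Hz) Gaussian carrier noise —
the standard surrogate for the raw sEMG interference pattern — and white
sensor noise sets the envelope-to-noise ratio. Defaults encode the study
conditions: 4 muscles, 3 phases, 12 cycles of 1 s at 1500 Hz, 2% timing
jitter, 5% amplitude jitter, 30 dB SNR.

Choices worth knowing about:

* **Phase centers (0.25, 0.50, 0.75) of the cycle.** Activity is
  concentrated inside the cycle with a quiet valley at the boundary, as in
  real pedaling envelopes. This is also a well-posedness requirement:
  minima-based segmentation needs the boundary valley to be the deepest
  minimum of the cycle.
* **Amplitude jitter per (cycle, phase, muscle).** A per-(cycle, phase)
  scalar would rescale a whole weight column and leave its *direction*
  exactly constant, making spatial stability degenerate at 1; elementwise
  jitter produces genuine inter-cycle spatial variability.
* **Carrier normalized to unit mean absolute value**, so the rectified,
  smoothed signal recovers the planted envelope without a calibration
  factor. The rectified carrier keeps an irreducible pointwise fluctuation
  (~10% relative after a 10 Hz smoother), so envelope-reconstruction
  checks compare cycle-averaged envelopes; single-cycle agreement is
  checked by correlation.
* **Resistance schedules** (levels 2–5) are package constants in
  `resistance_schedule()`: the VLAT power-phase weight grows, BF overtakes
  GAM in the power-end phase, TA drops only at the highest level, and both
  jitters shrink with level (higher force recruits more stable cycles).
  Only the directions are empirically motivated; the magnitudes are
  package defaults chosen once to be physiologically plausible.
* **One random stream per (seed, trial)** so trials can be generated
  independently and reproducibly; all package randomness runs on derived
  sub-seeds and never disturbs the caller's RNG state.

What the generator does **not** emulate: motor-unit biophysics, electrode
crosstalk and placement variability, fatigue drift within a trial,
kinematic variability of the limb, or inter-participant anatomical
differences. Passing recovery tests on this generator therefore shows the
pipeline is a correct implementation of its own model — it does not show
that three phases, or these effect directions, hold in any particular
human dataset.

## Numerical choices and degenerate inputs

* Filtering requires at least `3 * (order + 1)` samples; shorter series
  are rejected.
* An all-zero session (median 0), an all-zero factorization input, an
  unsegmentable composite (constant, or fewer than two qualifying minima)
  and an all-constant cycle pair all raise a classed error
  (`emgsynergy_degenerate`) instead of returning NaN.
* Cycles shorter than 4 samples cannot be resampled and are rejected.
* NMF updates guard denominators with $10^{-12}$; nonnegativity is
  preserved exactly by the multiplicative form.
* Per-cycle NMF failures drop the cycle with a warning; at least two
  cycles must survive.
* Problem sizes in the test suite: single trials of 12 cycles (18 000
  samples per channel), 20-seed recovery batches, 50-seed Monte-Carlo
  grids for the stability monotonicity checks, and a 100-trial
  segmentation batch — sizes at which every documented recovery property
  holds with margin.

## Known limitations

* The segmentation heuristics (composite = sum over muscles, autocorrelation
  cadence, prominence 0.2) are this package's decisions; the upstream
  segmentation literature they stand in for specifies no exact algorithm.
* Independent per-cycle NMF is noisier than fixed-W projection at low SNR;
  below ~15 dB the spatial stability index reflects estimation noise as
  much as physiology.
* The exact Mann–Whitney branch requires tie-free data; heavily tied
  metrics silently use the corrected normal approximation, which is
  anticonservative for very small samples with many ties.
* Order selection by a VAF threshold is known to be liberal when noise is
  low-rank; with only four muscles, `n_max = 4` keeps the search honest.
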