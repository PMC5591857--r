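---
title: "Quantifying neuronal memory for song: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neuronal memory for song: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssafi)
```

## The measurement problem

Neurons in the songbird caudal medial nidopallidum (NCM) adapt
stimulus-specifically: repeated playback of the same conspecific song evokes
progressively smaller multiunit responses, and the adaptation is independent
for each song. Because the adaptation state persists for many hours, the
*rate* at which a site re-adapts to a song one day later is a memory readout:
a song heard before adapts more slowly (the site is already partly adapted)
than a genuinely novel song. `ssafi` implements this readout as a
reproducible, testable pipeline:

1. **Response magnitude.** Each trial's multiunit trace is reduced to a
   scalar response magnitude — the baseline-subtracted RMS of the evoked
   window (`extract_magnitude()`).
2. **SSA rate.** For each site × song, magnitudes over the linear region of
   the adaptation profile (trials 6–25) are regressed on trial number by
   ordinary least squares; the slope is divided by the mean magnitude over
   the same window and expressed as percent change per trial
   (`fit_ssa_rates()`). Negative rates mean adaptation.
3. **Familiarity Index.** For each site × test set × familiar song,
   FI = mean(novel rates in the set) / (familiar rate)
   (`compute_fi()`). FI > 1 indicates memory: the familiar song adapts more
   slowly than novels. FI values are pooled into
   group × hemisphere × region medians (`pool_fi()`).
4. **Inference.** Sign tests of the pooled FI distribution against 1.0
   (exact binomial up to n = 100, continuity-corrected normal Z above),
   two-sample Kolmogorov–Smirnov contrasts between groups, hemispheres and
   regions, and Bonferroni correction over natural comparison pairs
   (`sign_test()`, `ks_two_sample()`, `bonferroni()`).
5. **Gene expression.** The companion qPCR module computes per-sample
   relative expression of immediate-early genes (e.g. *zenk*, *c-fos*)
   against a housekeeping gene and a vehicle reference by the ΔΔCT method,
   with two-sample (default) or one-sample contrasts per
   gene × region × hemisphere (`delta_delta_ct()`, `expression_contrast()`).

`run_analysis()` chains these stages, logs per-stage counts and exclusions,
and emits a machine-readable report.

## Why the rate is normalized the way it is

The raw OLS slope of magnitude vs. trial has the units of the recording
(volts per trial) and therefore depends on electrode impedance, amplifier
gain and site responsiveness. Dividing by the mean magnitude over the fit
window yields a dimensionless percent-per-trial rate with an exactly testable
invariance: `fit_ssa_rate(c * m) == fit_ssa_rate(m)` for any gain `c > 0`.
The FI, a ratio of two such rates at the same site, inherits the invariance.

The choice of denominator is not unique — the fitted intercept or the
first-window-trial magnitude would also remove the scale. All three are
exposed (`denominator =` `"window_mean"`, `"intercept"`, `"first_trial"`);
the window mean is the default because it is the most noise-robust of the
three (it averages 20 trials) and leaves the rate of an exactly linear
series identical under all conventions' spirit. Series whose denominator
falls below `epsilon` (default 1e-9 magnitude units) get an explicit
`near_zero_mean` exclusion rather than an unstable rate.

The fit window `[6, 25]` (inclusive, 20 points, 1-based trials) reflects the
shape of NCM adaptation: a fast drop over roughly the first five
presentations, then an approximately linear decline. Trials 1–5 are never
fit.

## FI granularity and exclusion rules

One FI record is produced per site × test set × familiar song, with the
novel denominator averaged *within the same set* at the same site —
same-session novels control for slow drift in responsiveness. An FI is only
meaningful when both rates reflect genuine adaptation, so records are
excluded — visibly, with reason codes, never silently — when the familiar
rate is ≥ 0 (`nonnegative_rate`), when the set has no usable novel rate
(`no_valid_novel`), when the novel mean is ≥ 0 (`nonnegative_novel_mean`),
or when the rate fit itself was excluded (`upstream_excluded`). Pooling
uses the median (even n: mean of the central pair) and reports empty cells
explicitly.

## The statistical battery

* **Sign test vs. FI = 1.** Nonparametric, appropriate for the skewed,
  heavy-tailed FI ratio distribution. Ties with the null are dropped and
  counted. Above n = 100 the continuity-corrected normal form is used and Z
  is reported; the exact binomial and the corrected approximation agree
  within 10% relative over the practically relevant range (|Z| ≲ 3) near
  the switch point, which the test suite verifies.
* **Two-sample K-S.** Distribution-free comparison of FI distributions
  (d statistic with asymptotic p); invariant under common monotone
  transforms, so it is indifferent to whether FI or log FI is analyzed.
* **Bonferroni.** Applied over the natural pairs of comparisons — the two
  hemispheres, or the two regions — with m = 2 by default.
* **t tests.** For approximately normal quantities (relative expression
  percentages). The expression contrast defaults to a pooled-variance
  two-sample comparison of treatment vs. reference percentages
  (df = n1 + n2 − 2); a one-sample form against the 100% reference level is
  available. With five birds per group the two-sample form reports df = 8.

### ΔΔCT conventions

Per sample, ΔCT = CT(target) − CT(housekeeping) within the same bird,
hemisphere and region; the per-sample expression level is 2^(−ΔCT),
assuming 100% amplification efficiency. Two reference conventions are
implemented. The default (`"fold_mean"`) divides by the *arithmetic mean of
the reference group's 2^(−ΔCT)*, which makes the reference group average
exactly 100% in every cell — a convenient invariant for "percent of
vehicle" displays. The classic convention (`"ct_mean"`) subtracts the mean
reference ΔCT in cycle space, which fixes the reference *geometric* mean at
100% (its arithmetic mean sits slightly above, by Jensen's inequality). The
two agree exactly when reference CTs are noise-free and differ by well under
a percent at typical CT noise; both are exactly invariant to a common CT
shift.

## The synthetic cohort generator

No public dataset exists for this paradigm, so validation rests on a
generator with known ground truth (`generate_cohort()`). It emulates the
test design: four song sets, each 2 familiar + 2 novel conspecific songs,
25 repetitions per song; four electrodes per hemisphere in NCM and
optionally in a non-NCM control region; treatment groups of configurable
size (defaults 8 drug, 6 vehicle, 6 extended-exposure birds).

Each site draws a baseline amplitude `A` from a lognormal distribution;
each series follows a piecewise profile: a geometric fast-adaptation bump
over trials 1–5 (starting at `fast_phase_drop_frac * A`, decaying with
ratio 0.35) and an exactly linear decline over trials 6–25, centred on the
window midpoint so the window mean equals `A`. That centring makes ground
truth exact: at zero noise the fitted normalized rate equals the configured
slope to machine precision, and the recovered FI equals the configured
`fi_true` of the cell exactly — properties the test suite asserts.
Familiar-song slopes are the novel slope divided by the cell's true FI.
Trial noise is multiplicative lognormal with unit mean and coefficient of
variation `noise_cv`, keeping magnitudes positive. Every site has its own
RNG substream derived from the root seed and the site's labels, so growing
a cohort never changes existing sites, and identical (config, seed) is
bit-identical.

### Default parameter choices

The electrophysiology literature for this paradigm reports normalized rates
and indices, not absolute voltages, so three generator defaults are the
package's own calibration, chosen once on field-plausibility grounds:

* `amplitude_log_mean = log(100)`, `amplitude_log_sd = 0.5`: site
  magnitudes spanning roughly 35–280 arbitrary units, a realistic spread of
  multiunit responsiveness. Absolute scale is immaterial — every downstream
  quantity is scale-invariant.
* `novel_slope_pct = −3.5` % per trial: a strong but sub-asymptotic decline
  (~50% loss across the linear region), consistent with the pronounced
  adaptation profiles this class of recordings shows for novel conspecific
  song.
* `noise_cv = 0.15`: 15% trial-to-trial variability, giving FI-record
  dispersion (IQR ≈ 0.3–0.5 in effect cells) on the order of what published
  pooled FI distributions display.

With these defaults, a per-series rate estimate has a standard error of
about 17% of the novel slope, and a cohort of 8 birds × 4 sites × 2
hemispheres recovers a cell's true FI to ±0.05 in the pooled median in
well over 95% of replicates — the resolution needed to distinguish the
effect sizes of interest (FI ≈ 1.1–1.3) from 1.

`scenario_config()` packages the reference scenario used by the worked
examples and `scripts/acceptance.R`: drug group with left-biased NCM memory
(true FI 1.28 / 1.15), vehicle group with none, extended-exposure group
with a bilateral 1.19 effect.

The epoch synthesizer (`generate_epochs()`) provides raw-voltage fixtures
for the magnitude-extraction stage: Gaussian baseline noise plus an evoked
Gaussian component whose expected baseline-subtracted RMS equals the target
magnitude; round-tripping through `build_series()` recovers the source
series within the sampling-noise floor. The qPCR generator encodes fold
changes as CT shifts (−log2 fold) on the target gene only.

### What the generator does and does not emulate

It reproduces the *statistical* structure the pipeline consumes: per-song
linear adaptation, familiarity/hemisphere/treatment-dependent slope ratios,
site-level amplitude heterogeneity, multiplicative trial noise. It does not
model spike-train statistics, song acoustics, session-time drift,
inter-bird effect heterogeneity, or site-within-bird correlation beyond
amplitude sharing. Passing parameter-recovery tests therefore demonstrates
the pipeline's correctness and calibration under these idealized
conditions, not the biological validity of the assay on real recordings.

## Numerical and degenerate-input choices

* OLS is computed by QR (`lm.fit`) on a shared design matrix across all
  series of a table at once; the test suite checks agreement with explicit
  normal equations to 1e-10 relative.
* A constant series has slope 0, rate 0 and undefined r².
* Sign-test ties with the null are dropped (classical convention); a sample
  entirely tied with the null is a degenerate-input error, not p = 1.
* The large-n sign test uses the continuity-corrected Z; with m = 2
  correction this maps Z = 3.85 to p ≈ 2.4e-4 and Z = 2.25 to p ≈ 0.049.
* K-S p-values are asymptotic; FI data can contain exact ties after
  exclusion-free noise-free simulation, where the d statistic is still
  exact and the p approximate.
* All validation errors name the offending field or the offending series
  keys; stages never drop data silently.

## Problem sizes used by the test suite

Simulation-based checks run at sizes chosen to give tight Monte-Carlo error
at interactive runtimes: 100 replicate cohorts for parameter recovery
(8 birds, NCM only), 2004 cells (167 cohorts × 12 cells) for the
sign-test size study, and 100 scenario replicates for the qualitative
pattern study (~2 minutes total). These are the package's validation
conditions; larger studies only tighten the Monte-Carlo error.

## Known limitations

* **Pooling ignores dependence.** Sites within a bird, and the two familiar
  records of a site × set (which share their novel-mean denominator,
  pairwise correlation ≈ 1/3), are pooled as if independent — as is
  conventional for this assay. The shared-denominator correlation makes the
  pooled sign test measurably anticonservative: under a global null the
  per-cell rejection rate at α = 0.05 is ≈ 6.8% rather than 5% (the test
  suite computes this). Mixed-effects modeling of the dependence structure
  is out of scope and left to the analyst.
* The normalization denominator used by the original lineage of this
  analysis (mean vs. intercept vs. first-trial amplitude) is not fully
  documented in the literature; the package defaults to the window mean and
  exposes the alternatives.
* ΔΔCT assumes perfect amplification efficiency; no standard-curve
  correction is implemented.
* The epoch model is a statistical stand-in (Gaussian evoked energy), not a
  biophysical simulation; filtering and artifact rejection are out of
  scope.
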