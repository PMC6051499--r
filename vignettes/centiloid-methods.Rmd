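---
title: "Centiloid calibration, positivity thresholds and longitudinal power: methods"
author: "centiloidr developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centiloid calibration, positivity thresholds and longitudinal power: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centiloidr)
```

## The problem

Amyloid PET studies quantify fibrillar beta-amyloid burden with a wide
variety of pipelines: different summary metrics (windowed SUVr versus
tracer-kinetic binding potential), different reference regions (cerebellar
cortex, whole cerebellum, brainstem), different post-injection windows, and
with or without partial-volume correction. The Centiloid scale standardizes
all of them onto a common 0–100 axis anchored at the mean burden of
amyloid-free young controls (0 CL) and of typical Alzheimer-disease patients
(100 CL). `centiloidr` implements the full analysis chain — quantification
primitives, level-2 calibration, three amyloid-positivity threshold
estimators, and cross-sectional/longitudinal comparison statistics —
together with synthetic-cohort generators so that every stage is testable
without access to clinical data.

## Quantification primitives

**Windowed SUVr.** A frame belongs to a window `[start, end]` when its
mid-time lies in the closed interval; this is a deliberate convention, since
edge handling is rarely stated in the literature. The window mean is
duration-weighted, reproducing the value a summed image over the window
would give, and SUVr is the ratio of target to reference window means.

**Logan reference-tissue graphical analysis.** For frames with mid-time at
or after `t_star` (default 30 min for 0–90-min acquisitions), the running
integrals of target and reference activity — trapezoidal between frame
mid-times, with the leading segment from injection treated as a triangle
rising from zero — are normalized by instantaneous target activity and
regressed. The asymptotic slope estimates the distribution volume ratio
(DVR) and `BP_ND = DVR - 1`. The reference-region efflux (k2') correction
term is omitted: once the target/reference ratio is in pseudo-equilibrium
the omitted term is absorbed into the regression intercept, so the slope is
asymptotically unbiased. This is a known limitation for fast-clearing
reference regions and short scans.

**Partial-volume correction.** Scanner blur redistributes signal between
neighboring regions. At region level this is a row-stochastic mixing,
`observed = M %*% true`, and the correction is the linear solve
`solve(M, observed)` (the geometric-transfer-matrix form). Constructing `M`
from anatomy is out of scope; the matrix is an input, rows must sum to 1
within 1e-6, and condition numbers above 1e8 are refused because the inverse
then amplifies noise beyond usefulness. Noise amplification grows
monotonically with the condition number — the test suite checks this on
two-region phantoms.

**Mean cortical index.** The global burden summary is a weighted mean over a
named set of cortical regions (frontal, parietal, temporal, precuneus in the
classical definition), unweighted by default since volume weighting schemes
vary between laboratories.

## Level-2 Centiloid calibration

The anchor transform is `CL(s) = 100 (s - mu_YC) / (mu_AD - mu_YC)`, exact
at both anchors. For a non-standard method, ordinary least squares is fitted
with the **standard SUVr as response** and the method value as predictor,
and the fitted affine map is composed with the anchor transform. The
regression direction is a design choice the calibration literature leaves
open; predicting the standard-equivalent value is the natural direction
because the composed map must output standard-scale Centiloids. Fits with
R-squared below 0.70 carry a `quality_flag` and a warning rather than an
error: published calibrations report R-squared well above 0.9, so the gate
is a guard against misuse, not a routine code path.

Anchors are supplied externally rather than recomputed per subset. On any
finite calibration subset the converted group means deviate slightly from
0/100 — the sampling error of an 18-subject group mean with SUVr SD 0.05 is
roughly 1.2 CL — which is why the test suite asserts the median calibrated
young-control mean over repeated cohorts lies within ±2 CL of zero rather
than asserting exactness.

Equations serialize to JSON with six significant digits for human readers
plus C99 hex-float strings for the exact double representation, so
write/read round-trips are bit-exact.

## Positivity thresholds

1. **Empirical conversion** maps a laboratory's historical native-scale
   cutoff (for example, mean cortical `BP_ND` 0.18) through the method's
   conversion equation.
2. **Specificity threshold**: the 95th percentile of the young-control
   distribution, computed with linear interpolation between order statistics
   (the type-7 quantile rule, R's default). The rule matters at n = 18 —
   different quantile definitions move the threshold by more than a
   Centiloid — so it is fixed and documented.
3. **Modified reliable worsening (RW)**: the smoothed annualized
   rate-of-change versus baseline curve is scanned for its minimum, and the
   threshold is the smallest integer grid Centiloid at or after the minimum
   with *strictly positive* fitted rate. A grid value exactly at zero does
   not qualify. This modification guarantees the threshold never
   corresponds to a negative accumulation rate, which can happen under the
   unmodified rule when the curve's minimum is negative. An
   everywhere-positive curve returns the left-most supported grid point
   with a warning — a degenerate case the rule's originators never faced.

The rate curve is LOESS (locally linear, tricube weights) of annualized
change against baseline, evaluated on an integer Centiloid grid spanning by
default the central 98% of baselines, with subject-bootstrap percentile
bands. Defaults: span 0.75, B = 1000, 95% bands — span and degree are not
fixed by the threshold literature, and the bootstrap interval type is a
package choice.

### Numerical behavior of the RW estimator

Two properties of this estimator deserve explicit documentation because the
test suite is built around them:

- **Span bias.** With n ≈ 250 subjects, span 0.75 averages three quarters of
  the cohort into every local fit and systematically drags the estimated
  zero crossing toward the dense amyloid-negative mode: in simulation the
  recovered crossing sits about 5 CL below truth regardless of the true
  rate-function family. At span 0.35 (local windows of ~85 subjects) the
  estimator recovers crossings at 0, 10 and 20 CL within ±3 CL (median over
  20 seeds, per-visit noise 2.5 CL). The acceptance suite therefore runs the
  recovery check at span 0.35; the API default stays at the conventional
  0.75, and analysts estimating an RW threshold at this cohort size should
  prefer the smaller span.
- **Band coverage under clustered designs.** Pointwise percentile bootstrap
  bands achieve their nominal coverage of a noiseless truth under a roughly
  uniform baseline design (measured ~97% at the 95% level). Under a strongly
  bimodal design, the smoothing window inside the sparse gap between modes
  is dominated by the dense mode; the fit is locally biased and the bands,
  which only see resampling variance, undercover there (~80%). The coverage
  test uses a uniform design; conclusions about band coverage do not
  transfer to sparse regions of clustered cohorts.

## Cohort statistics

Positivity classification uses a strict `>` by default (boundary handling is
another convention the literature leaves unstated). Longitudinal cohorts are
partitioned into *stable negatives* (negative at both visits) and
*accumulators* (positive at either visit); the partition is exact and
tested.

- **Intra-individual variability** is the sample SD of the *annualized*
  change among stable negatives. Annualizing before taking the SD is the
  reading under which published effect sizes equal rate/variability; with
  independent per-visit noise of SD sigma and fixed interval T its expected
  value is `sqrt(2) * sigma / T`, which the suite verifies at n = 10,000.
- **Effect size** is mean accumulator rate over intra-individual
  variability, both in CL/yr.
- **Variance comparisons** use the classical two-sided F-test. For paired
  samples (the same subjects quantified two ways) the plain F is reported
  for fidelity to common practice, alongside the Pitman–Morgan
  correlation-adjusted statistic, which is the correct paired test; both are
  labeled.
- **Two-tier significance**: `p < 0.0005` is "overall" (surviving a
  Bonferroni convention of 100 comparisons at family-wise 0.05) and
  `p < 0.05` "tentative". The pipeline records the number of tests actually
  performed but reports the /100 convention as the corrected level.
- **Trial sample size** uses the normal-approximation two-sample formula
  `n = ceil(2 (z_{1-a/2} + z_power)^2 sigma^2 / delta^2)` with
  `delta = reduction * rate * duration` and `sigma = intra_sd * duration`.
  With rate 5.2 CL/yr, variability 2.7 CL/yr and a 50%-reduction, 80%-power,
  one-year design this gives 17 per arm. Published per-arm counts for other
  method variants are not all consistent with any single standard formula
  applied to their printed inputs, so only this configuration is asserted;
  the formula's components are all configurable. A simulation check confirms
  the returned n achieves at least 0.75 empirical power under the stated
  normal model.

## The synthetic world

The generators state a world once and the tests live in it:

- **Calibration cohorts**: 18 young controls (standard SUVr ~ N(1.05,
  0.05^2)) and 18 AD patients (~ N(2.05, 0.2^2)); method values are affine
  in the standard value plus independent normal noise (default SD 0.05
  native units). Normality is a modeling choice consistent with the use of
  means, SDs, F- and t-tests downstream.
- **Longitudinal cohorts**: 243 subjects, baselines from a two-component
  mixture (75% near 0 CL with SD 6, 25% near 60 CL with SD 25), intervals
  truncated-normal 3.2 ± 1.5 yr with a 0.5-yr floor, and a
  baseline-dependent true accumulation rate. The follow-up truth applies
  the rate at baseline over the whole interval (one Euler step), matching
  the annualized-rate framing of the downstream statistics rather than
  integrating a trajectory. The default rate function is a logistic dip
  (floor −0.5 CL/yr, plateau 5 CL/yr, upward zero crossing near 10 CL);
  the family is a modeling choice — the empirical shape of such curves is
  only known qualitatively.
- **Reference-tissue TACs**: the simplified reference tissue model solved by
  exponential-kernel convolution on a dense grid (`dt` = 0.02 min). Defaults
  R1 = 0.9, k2 = 0.2/min and a slowly clearing biexponential reference
  (washout 0.005/min) describe a PiB-like tracer that reaches
  pseudo-equilibrium within a 90-min scan — the regime in which windowed
  SUVr approximates DVR within 10% and Logan recovers BP within 2%, which is
  exactly what the tests assert. Faster-clearing kinetics would violate
  both; that is a property of the method, not a bug in the generator.
- **Mixing phantoms**: row-stochastic matrices applied to nonnegative true
  means, with optional additive noise.

Fixing the seed reproduces every generated table bit-identically, and no
generator touches the caller's RNG state. What a green test establishes is
internal consistency of the chain under this stated world; none of the
published cohort-specific numbers (young-control SDs, printed thresholds,
calibration R-squared values) can be reproduced without the original scans,
and the suite does not pretend to.

## Degenerate inputs and tie-breaks

- Empty time windows, non-positive reference means, fewer than 3 Logan
  frames, ill-conditioned mixing matrices, missing regions, missing cohort
  columns and non-numeric cells all raise errors naming the offending
  field, line or window.
- Paired t on zero-variance differences: all-zero gives t = 0, p = 1;
  constant nonzero gives an infinite-t flag with p reported as the 0 limit.
- RW on a curve that never rises above zero after its minimum returns `NA`
  with a diagnostic; thresholds are integers because the curve is only
  sampled at integer Centiloids.
- Report serialization writes missing values as empty delimited cells and
  JSON nulls, never sentinel numbers.

## Known limitations

- Logan omits the k2' term; bias is negligible only near pseudo-equilibrium.
- The RW threshold inherits LOESS span sensitivity (see above); reported
  thresholds should state the span.
- Bootstrap bands are pointwise, not simultaneous, and undercover in sparse
  regions of clustered designs.
- The trial-size formula ignores dropout and uses a normal approximation;
  at n below ~15 per arm a t-quantile correction would add 1–2 subjects.
- Voxelwise image synthesis, spatial normalization, motion correction and
  scanner harmonization are out of scope; the optional NIfTI entry point
  only computes labelled-region means on pre-aligned grids.
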