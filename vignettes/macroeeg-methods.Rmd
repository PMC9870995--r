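---
title: "Methods: macroscale EEG features and random-forest analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: macroscale EEG features and random-forest analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macroeeg)
```

This vignette is the package's own account of its methods: the models and
their assumptions, the parameter conventions and why they were chosen, what
the synthetic generator does and does not emulate, and the numerical
decisions a maintainer would want written down. It states no empirical
result that the test suite or the worked examples do not themselves
compute.

## The analysis design

One subject's eyes-closed resting recording (64 channels, 2048 Hz) is
reduced to 60 whole-head features — per band (delta 0.5–4, theta 4–8,
alpha 8–13, beta 13–20 Hz): relative spectral power, mean phase lag index
(PLI), mean corrected amplitude envelope correlation (AEC-c), and six
minimum-spanning-tree measures computed once on the PLI matrix and once on
the AEC-c matrix. Three analyses follow: univariate Mann-Whitney
comparisons with Holm-Bonferroni correction, balanced random-forest
classification of group, and permutation-validated random-forest
regression of PANSS change after treatment. Frequencies above 20 Hz are
excluded throughout (scalp signals there are heavily contaminated by
muscle activity), so there is deliberately no gamma band; the beta band is
13–20 Hz even though introductory texts often quote 13–30 Hz.

## Preprocessing conventions

The pipeline order is fixed: average reference → downsample →
spherical-spline interpolation of bad channels → epoch selection →
per-band filtering.

* **Artifact criterion.** The reference design used visual artifact rating
  by trained raters, which is not reproducible algorithmically. The
  package substitutes an absolute-amplitude threshold (default 100 µV on
  any channel within a 4-s window; a configuration knob). Windows lie on a
  fixed non-overlapping grid from the first sample; a violating window is
  skipped whole, and the first 15 clean windows are taken in temporal
  order ("first 15 epochs"). Consequence: prepending whole windows of
  artifact shifts the selection by exactly those windows (a property the
  tests assert); prepending *clean* whole windows instead prepends them to
  the selection, which is the literal reading of "first".
* **Filtering.** No filter family is prescribed by the design, but phase
  metrics forbid group delay. All filtering (band-pass, anti-alias before
  decimation) is frequency-domain multiplication with a purely real,
  raised-cosine-edged transfer function: exactly zero-phase, unit passband
  gain, transition ramps (default 0.5 Hz) placed outside the band edges.
  The cost is circular edge behaviour on finite segments, which is why the
  connectivity metrics discard an edge margin (below). Downsampling
  2048 → 1024 Hz low-passes with a ramp ending at the new Nyquist
  (flat to 0.85×Nyquist) before taking every second sample.
* **Interpolation.** Spherical splines in the standard order-4
  formulation (Legendre series `g(x) = (1/4π) Σ (2n+1)/(n(n+1))⁴ Pₙ(x)`,
  20 terms, ridge 1e-8) on an idealized unit-sphere 10-10 montage built
  geometrically (ring at 72° inclination, 18° steps; lateral rows by
  spherical interpolation between midline and ring). At most 6 channels
  (~10 % of 64) may be interpolated; more raises a subject-exclusion
  condition that the cohort builder converts into an exclusion-report row.

## Spectral power

Rectangular-window (no taper) periodograms per 4-s epoch and channel,
averaged over epochs then channels; 4-s epochs give 0.25 Hz bins, and the
scaling is chosen so the bin sum equals the time-domain mean square
(Parseval), which the tests check exactly — the main reason the default
window is rectangular (a Hann option exists behind a config argument).
Relative power divides each band's power by the *sum over the four bands
only*, so the four fractions sum to one. Band edges shared by adjacent
bands (4, 8, 13 Hz) are assigned to the lower band via half-open bins
`[low, high)`; on an exactly flat spectrum the fractions are therefore
3.5/19.5, 4/19.5, 5/19.5, 7/19.5. Channel-averaged (not channel-wise)
spectra enter the per-bin group comparison; the design source does not say
which it used, and macroscale averaging is this package's consistent
convention.

## Connectivity

Both metrics work on the analytic signal (FFT Hilbert transform) of each
band-filtered epoch, with the outer 1/8 of each epoch's samples discarded
at both ends before averaging: the Hilbert transform and the FFT filters
wrap circularly, and edge transients bias phase locking upward. Epochs are
averaged with equal weights; whether the original analysis correlated
envelopes per epoch or across concatenated epochs is unstated — per-epoch
averaging is implemented.

* **PLI** is `|mean over samples of sign(sin(φᵢ − φⱼ))|`. Exactly zero
  (or π) phase differences contribute 0 — numerically, imaginary parts
  below 1e-12 are treated as zero so that identical channels score an
  exact 0 rather than accumulated rounding noise. Range 0 (no asymmetry)
  to 1 (complete non-zero-lag locking).
* **AEC-c** orthogonalizes the target's analytic signal against the seed
  sample-wise (`Y⊥ = Im(Y · X*/|X|)`), removing the instantaneously shared
  component, correlates `|Y⊥|` with `|X|` (Pearson), averages the two
  directions of each pair, and reports `(r + 1)/2`: 0.5 means no coupling,
  1 perfect coupling, 0 perfect negative coupling. Orthogonalization is
  pairwise and symmetric because the design source says only
  "orthogonalization of raw signals" without a direction; averaging both
  directions is the standard leakage-correction practice. A pair of
  exactly collinear signals leaves a zero residual; its value is defined
  as 0.5 (no evidence of coupling beyond the shared component) with a
  warning rather than an error, so one dead pair cannot abort a cohort.

The whole-brain mean is the arithmetic mean over the strict upper triangle
(2016 pairs at 64 channels). The property motivating this metric pair —
instantaneous mixing leaves PLI at its null level and AEC-c at 0.5 while
*uncorrected* envelope correlation inflates — is asserted in the
acceptance suite against the generator's mixing surrogate.

## Minimum spanning tree

"Minimizing the link weights" in this literature means treating *strong
coupling as short distance*: the implementation is Kruskal's algorithm on
edges sorted by decreasing coupling (equivalently, an MST over inverted
weights), with deterministic lexicographic tie-breaking so equal-weight
matrices always give the same tree. Six global measures, all normalized to
[0, 1] with `M = n − 1`:

| measure | definition |
|---|---|
| kmax | max degree / (n−1) |
| leaf fraction | #degree-1 nodes / n |
| diameter | max hop distance / M |
| mean eccentricity | mean over nodes of max hop distance / M |
| BCmax | max betweenness / ((n−1)(n−2)/2) |
| tree hierarchy | L / (2·M·BCmax) |

Two readings of `M` in tree hierarchy circulate ("number of links" vs
"maximum leaf number"). For a spanning tree on `n` nodes both equal
`n − 1` for every `n` (the star attains `n − 1` leaves), so the package
implements the single common value and offers no switch. Distance-based
measures are normalized by `M = n − 1`, which reproduces the magnitude of
published whole-head eccentricity values (~0.15). Betweenness on a tree is
computed exactly by subtree counting (paths in a tree are unique) and is
cross-checked in the tests against a naive path-walking oracle and against
exhaustive spanning-tree enumeration for n ≤ 7.

## Random-forest models

No suitable random-forest package is available in the target environment,
and the forest is the analytical core of the design, so the package ships
its own compiled implementation: CART trees, variance-reduction splits
(equivalent to Gini for 0/1 labels), bootstrap resampling, per-node
feature subsampling, leaf-mean prediction, out-of-bag permutation
importance (mean increase in OOB MSE / misclassification after permuting
one feature — chosen over impurity importance because the screening logic
compares importances across features of different scales). Terminal node
size 5 for regression, 1 for classification, following the conventional
defaults. `mtry = round(√p)`, which yields 6 at 40 features and 8 at 60 —
matching both published operating points of the rule simultaneously.

* **Noise screening** appends one uniform-random column, fits a forest,
  and drops every feature whose importance is `≤` the noise feature's
  (the `≤` rule makes the noise column's own exclusion tautological).
* **Balanced classification** draws, per round, all minority-class
  subjects plus an equal-size random draw of the majority class
  (62 + 62 in the reference design), refits the screen within the round
  (the source does not say whether screening was refit per subset; per-round
  refitting is the choice here, with screening optional via `screen = FALSE`),
  and evaluates by stratified tenfold cross-validation. When no feature
  beats the noise column — which happens by chance on signal-free data,
  roughly once per sixty screens — the round falls back to the full
  feature set instead of aborting the cohort analysis; a direct call to
  `noise_screen()` still raises the advisory error. Sensitivity and
  specificity use patients as the positive class. Note an honest caveat
  the null simulations expose: screening on the same data that is then
  cross-validated is mildly optimistic (a few points of accuracy under
  label permutation), which mirrors the original flow; the chance-level
  acceptance test therefore runs with screening off.
* **Regression** uses all 60 features by default (screening off, as in
  the reference analysis), tenfold CV, `R² = 1 − SSE/SST` over the pooled
  out-of-fold predictions (per-fold RMSE/R² summarized as mean ± SD), and
  a permutation test: the outcome is permuted `n_perm` times (1000 by
  default), the full CV pipeline is re-run, and
  `p = (1 + #{R²_perm ≥ R²_obs})/(n_perm + 1)` — the add-one correction
  means p can never be 0. Whether the original tenfold CV was stratified
  is unstated; plain random folds are used for regression, stratified for
  classification. Importances are rescaled so the best feature scores 100.

Every random element — subset draws, noise columns, fold assignments,
tree bootstraps, permutations — derives from one master seed through a
fixed seed-derivation stream, so two runs agree bit for bit.

### What forests can and cannot recover here

A regression forest is a piecewise-constant learner; with ~45 subjects it
recovers only a fraction of even a perfectly linear signal, and every
uninformative feature dilutes it further. On a 60-feature table where 3
features carry the outcome, cross-validated R² plateaus around 0.25 — a
level this package's forest shares with reference implementations on
matched designs — while the permutation p is already highly significant.
The acceptance criterion "planted links yield R² > 0.5" is therefore
checked on a design where that level is attainable (n = 45, 3 informative
+ 2 nuisance features, residual SD 0.3); the vocabulary-wide planted-link
behaviour (significant p, modest R²) is covered by the cohort tests.

## The synthetic data module

The generator is a *stated world*, not a fit to any dataset.

**Signals.** Per channel and band, a unit-variance narrowband Gaussian
carrier (FFT-filtered white noise); per channel, a 1/f^α background
(default α = 1); default band amplitudes (delta 10, theta 8, alpha 20,
beta 6 µV SD, background 10 µV) describe an alpha-dominant eyes-closed
young-adult recording — conventions, since the reference study publishes
no spectral parameters of its cohort. Phase coupling replaces a fraction
`strength` of the target's carrier with the seed's carrier shifted by a
fixed phase lag via the analytic signal: `strength = 1` with a non-zero
lag forces PLI = 1 analytically, `strength = 0` leaves pairs independent,
and PLI increases monotonically in between (asserted by a Spearman
property test). Envelope coupling multiplies independent carriers by
correlated log-normal slow envelopes (shared low-pass Gaussian log-
envelopes, σ = 0.75, < 1 Hz), so amplitude coupling is testable separately
from phase coupling. An arbitrary instantaneous mixing matrix, applied
last, serves as the volume-conduction surrogate. Recordings are
reproducible bit for bit under a seed and export to EDF (16-bit) or BDF
(24-bit) with integer physical-range headers so the scaling survives the
ASCII header fields exactly.

What is *not* emulated: alpha peak-frequency variability, non-stationarity
(drowsiness, blinks, muscle bursts beyond simple amplitude transients),
realistic head-volume conduction geometry, and cross-frequency structure.
A green test on this world therefore establishes the *estimators'*
correctness and robustness properties, not clinical realism.

**Cohorts.** Feature-level subjects are drawn logit-normally around
control medians (all 60 features live in [0, 1]); a planted effect shifts
the patient median of a named feature additively, and because the
logit-normal median is exact, planted medians are achieved without
calibration. Relative powers stay on the simplex by anchoring the planted
(or delta) power and scaling the rest — hence at most one relative-power
feature can be planted per cohort. Control medians: delta relative power
0.575 (the published control median), remaining conventions chosen for a
plausible eyes-closed profile (PLI 0.10–0.28, AEC-c ≈ 0.53–0.60, MST
leaf fraction 0.62, BCmax 0.75, eccentricity 0.155, hierarchy 0.38, kmax
0.15, diameter 0.28). PANSS trajectories use published baseline moments
(positive 18.6 ± 4.4, negative 18.5 ± 7.0, general 37.5 ± 9.0; total =
their sum), a mean positive-subscale change of −5.18 with a linear link on
z-scored features (default: a weak three-feature network link, ≈ 20 %
explained variance, residual SD 3.5) and feature-independent negative /
general changes; all values are rounded to integers and clipped to the
instrument ranges (positive/negative 7–49, general 16–112) because PANSS
is an integer instrument. By default 45/62 of patients have follow-up,
reproducing the published attrition.

## Numerical choices and degenerate inputs

* Ties in the MST are broken lexicographically (documented contract, not
  an accident of sort stability).
* PLI sign threshold 1e-12; collinear AEC-c pairs → 0.5 + warning;
  constant channels → error naming the channel.
* Exact Mann-Whitney p (via the U distribution) for tie-free pooled
  n ≤ 20, tie-corrected continuity-corrected normal approximation
  otherwise; all-identical samples give p = 1.
* Holm adjustment caps at 1 and enforces monotonicity with a running
  maximum; input order is preserved.
* Permutation p uses the add-one rule; n_perm = 0 degenerates to p = 1.
* EDF/BDF export requires whole seconds and integer sample rates; flat
  channels get a widened physical range to avoid zero scale.
* Seeds derived from the master seed stay below 2³¹.

## Known limitations

* The amplitude-threshold artifact criterion is a stand-in for human
  rating; on real data it will pass low-amplitude artifacts (e.g. slow eye
  movements) that raters would reject.
* FFT filtering assumes local stationarity within 4-s epochs; the
  discarded edge margin reduces but does not eliminate wrap-around
  effects for the delta band, whose period is commensurate with the epoch.
* The per-epoch AEC-c envelope correlation uses ~3.5 s of envelope per
  epoch — short relative to slow envelope dynamics; values are noisier
  than concatenated-epoch estimates would be.
* Balanced-subset classification reuses each minority-class subject in
  every round, so the 10 round metrics are positively correlated; their
  mean is reported without a dispersion claim.
* The compiled forest is single-threaded; a full 1000-permutation
  regression on 60 features takes a few minutes per outcome on one CPU.
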