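---
title: "Evaluating feature-selection methods for ictal EEG classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating feature-selection methods for ictal EEG classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ictalfs)
```

## The problem

Seizure-detection studies extract large per-channel, per-band feature
vectors from scalp EEG (hundreds of columns for 18–21 bipolar channels and
five bands) and train binary classifiers to separate ictal from background
epochs. Because the feature space is redundant and the classes heavily
imbalanced, two questions dominate the modeling work: *which* features carry
the discriminative signal, and *how few* of them suffice. `ictalfs`
implements the complete evaluation loop for six importance-ranking methods
(FSMs) — decision-tree Gini importance, linear-SVM weights, LIME, kernel
SHAP, random-forest permutation importance, and reciprocal rank fusion —
crossed with five classifier families under 5×2 cross-validation, stepwise
feature elimination, a paired F-test, and Jaccard feature-set agreement.

Everything runs on synthetic recordings with *planted* discriminative
structure, so the pipeline's claims are checkable: the generator knows which
channel/band amplitude features it made informative, and the test suite
verifies that every ranking method finds them.

## The synthetic generator: what it emulates, and what it does not

`generate_recording()` emulates the shape of annotated scalp EEG datasets:
256 Hz sampling, bipolar channels named after the 10–20 longitudinal
("double banana") montage, hour-scale durations, a handful of seizure
intervals listed in a plain-text sidecar, and a roughly 9:1 non-ictal:ictal
epoch imbalance after windowing.

Background activity is `1/f` colored noise (so all five analysis bands carry
non-degenerate power) plus a modest-amplitude 10 Hz sinusoid with a random
phase per channel — a caricature of the posterior alpha rhythm. Seizures
superimpose a higher-amplitude sinusoid at a configured frequency on the
configured channels, with a 0.5 s raised-cosine onset/offset ramp. Amplitude
units are nominal microvolts; the absolute scale is irrelevant because
evaluation min–max-normalizes every feature.

Defaults are chosen to match the recording conditions the pipeline is aimed
at: 21 channels, 256 Hz, hour-scale duration, seizures of tens of seconds.
Seizure onsets are placed uniformly at random with a minimum 4 s gap (twice
the window length), so no epoch can straddle two seizures. Signals are
generated directly in bipolar form; a monopolar mode exists solely to
exercise `to_bipolar()`.

What the generator does **not** emulate: artifacts (EMG, eye blinks,
electrode pops), non-stationary background dynamics, spatial correlation
between channels, evolving seizure morphology, or inter-patient variability.
Passing tests on this data therefore demonstrate the *correctness of the
pipeline machinery* — ranking methods recover what was planted, elimination
curves behave, statistics are computed as defined — not clinical
performance. On planted sinusoidal bursts the classification problem is
nearly separable (F1 ≈ 1 for most classifiers), which is intended: the tests
assert recovery and stability properties, not headline scores.

## Preprocessing decisions

* **Filtering** is zero-phase (forward–backward) throughout: a second-order
  Butterworth high-pass at 0.5 Hz, then a second-order IIR notch (quality
  factor 30, biquad closed form) at the power-line frequency, then
  second-order Butterworth band-passes for the five bands. Zero-phase
  filtering keeps epoch/annotation alignment exact; the cost is that the
  effective attenuation is the squared magnitude response. Signals are
  padded by odd reflection (up to 3072 samples) before each pass so DC
  offsets and edges leave no boundary transients.
* **Epoching**: ictal portions are cut into 2 s windows with a 1 s stride
  (the 50% overlap convention) starting at each annotated onset; non-ictal
  portions are tiled with non-overlapping 2 s windows that lie fully outside
  every seizure interval. An epoch is ictal iff at least half of its samples
  fall inside an annotated interval; with per-region cutting this rule is
  satisfied trivially and no epoch ever mixes classes — boundary slivers are
  discarded rather than mislabeled.
* **Rebalancing** keeps every ictal epoch and draws a seeded uniform
  subsample of non-ictal epochs down to at most 9× the ictal count.
* **Order of operations**: the continuous recording is filtered first, then
  epoched, then each epoch is band-decomposed. The complete 0.5–30 Hz copy
  goes through the same band-pass machinery as the four sub-bands so all
  five are treated identically.

## Feature conventions and degenerate inputs

Eight metrics per channel and band, named `band_channel_metric`
(e.g. `alpha_FP1-F3_skew`); column order is band-major, then channel, then
metric, and deterministic.

* Skewness and kurtosis are moment ratios; kurtosis is excess (normal → 0).
  A constant epoch returns 0 for both rather than NaN.
* Zero crossings count strict sign changes; an exact-zero sample inherits
  the previous sign, so a touch of the axis is not double-counted.
* The PSD is a single Hann-windowed periodogram of the full 2 s epoch
  (0.5 Hz resolution at 256 Hz); Welch averaging has nothing to average at
  this epoch length. A zero-power epoch returns 0 for both spectral metrics.
* Sample entropy uses m = 2 and tolerance r = 0.2·SD with Chebyshev
  matching and self-matches excluded; it is computed in C++ (the O(n²) pair
  count dominates fs2 extraction otherwise). If no template pair matches at
  either length the value is capped at `log(n)`; a constant epoch has
  tolerance 0 with equal samples declared matching, hence SampEn 0.
* Correlation pruning scans columns in order and drops the *later* column of
  any pair with |Pearson r| above 0.95. Absolute correlation is used so that
  anti-correlated duplicates are also removed. Zero-variance columns
  correlate with nothing, are retained, and are reported in an audit list.
  The operation is idempotent. The pipeline prunes before splitting, which
  matches the narrative order of the study design it follows; both entry
  points exist if fold-wise pruning is wanted.

## Ranking conventions

All six methods return a `ranking` with non-negative scores (absolute-value
convention) and an order that sorts scores non-increasingly, ties broken
stably by original column position.

* **Gini importance** is computed by walking the fitted CART tree: each
  node's contribution is `p(t)·Δi(t)` with `p(t) = N_t / N`; scores are
  normalized to sum to one. Trees are fitted on positional aliases because
  bipolar channel names are not syntactic R names.
* **LIME** draws 1000 Gaussian perturbations per explained instance around
  the instance (per-feature scale = the training SD), weights them with
  `exp(−d²/w²)` at kernel width `w = 0.75·√M`, fits a weighted linear
  surrogate to the model's positive-class probability, and takes coefficient
  magnitudes. No discretization.
* **Kernel SHAP** solves the Shapley-kernel weighted least squares under the
  additive constraint. Absent features are imputed by averaging the model
  output over all 50 k-means background centroids — a deterministic choice
  (rather than sampling one random donor instance) made for testability.
  Coalitions are fully enumerated up to 12 features, where the attributions
  provably equal exact Shapley values (verified against a brute-force 2^M
  oracle); beyond that, every singleton and leave-one-out coalition plus
  `2M + 2048` size-weighted samples are used.
* **LIME/SHAP aggregation** is abs-then-mean across instances: absolute
  values are taken per instance before averaging, so opposite-signed local
  attributions cannot cancel. Both methods explain the probability output of
  the same classifier family that is later evaluated with the ranking; the
  explained instance set defaults to a seeded subset (25 for LIME, 10 for
  SHAP) as a compute-scale parameter — the oracle tests use full sets.
* **Permutation importance** trains a 10-tree random forest and measures the
  mean increase in misclassification rate on a *separate holdout* (the rows
  outside the ranking subsample) over 5 permutation repeats per feature.
* **Reciprocal rank fusion** combines the five rankings by
  `r(f) = 1/Σ_j 1/r_j(f)`; the stored score is `Σ_j 1/r_j(f)` so the usual
  descending-score ordering applies.
* Where model training is required during ranking, a seeded stratified 50%
  subsample is used, min–max scaled.

## Evaluation decisions

* 5×2 CV folds are **stratified**: with 9:1 imbalance, unstratified 2-fold
  splits risk near-class-free folds. Each of the five repetitions reshuffles
  (seeded) before splitting.
* Min–max scaling is fitted on the training fold only and applied to both;
  test values may leave [0, 1] (no clipping); constant training features map
  to 0.
* Rankings are computed once, up front, not per fold.
* F1 is reported for the ictal (minority, positive) class; with this
  imbalance, accuracy alone is misleadingly high.
* The elimination schedule starts at the full feature count, descends
  through every multiple of 50, then 25, 12, 6, 1.
* Classifier configurations are fixed per feature set (DT min node size 8/2,
  RBF-SVM C = 2 with `1/(M·var(X))` gamma, KNN k = 15 Manhattan-uniform or
  k = 10 Euclidean-distance-weighted, RF with 150 trees, network trained 200
  epochs with entropy loss); no grid search is re-run. KNN prediction is a
  small internal implementation because no available engine offers Manhattan
  plus distance weighting. The network is a single-hidden-layer
  feed-forward model (50 logistic units) — the package's own configuration
  of that family; deeper stacks would need a different backend.

## The 5×2cv F-test and its calibration

For paired error grids the combined statistic
`F = Σ_ij d_ij² / (2 Σ_i s_i²)` is referred to F(10, 5). Degenerate inputs
are handled explicitly: all-zero differences give F = 0, p = 1; zero
within-repetition variance with non-zero differences is flagged degenerate
(p = 0).

A caveat worth stating plainly: the F(10, 5) reference assumes an
independence between numerator and denominator that fold-reuse violates, and
the test is *conservative by construction* — under an idealized null with
iid normal differences it rejects at roughly 1.6%, not 5%. Under the
package's simulated null (two equal-accuracy midpoint-threshold stumps on
independent, equally informative features; n = 120, 1 SD class separation)
the measured rejection rate sits around 0.02–0.04 across seeds at 500
simulations — at or just below the nominal level, and sensitive to the
dependence structure of the null design. The null design was fixed on a
priori grounds and is not adjusted to move the measured rate; in practice
this conservativeness means significant 5×2cv F-test results can be trusted,
while the test has limited power to certify small differences.

## Problem sizes

The test suite and acceptance script run deliberately scaled-down studies,
chosen so the full loop executes in minutes on one CPU: a 4-channel, 5-minute
recording for the unit fixtures; a 6-channel, 30-minute recording with
five seizures and two planted channel/band combinations (~950 epochs, 320
features before pruning) for the recovery checks; 500 simulated dataset
pairs for the F-test null. The `analysis/` scripts run the same study at
8 channels and one hour (~1750 epochs after 9:1 rebalancing). All stages
scale linearly in channels × duration except kernel SHAP, whose cost is
instances × coalitions × background size.

## Known limitations

* The generator's stationary sinusoid-burst seizures make the classification
  task nearly separable; elimination curves on synthetic data flatten at
  F1 ≈ 1 and therefore exercise the machinery, not the difficulty, of
  feature reduction.
* EDF input is a named hook only; recordings enter via the native delimited
  format or in memory.
* Kernel SHAP beyond 12 features uses sampled coalitions with kernel
  weights; attributions are then estimates, not exact Shapley values.
* The combined 5×2cv F-test is conservative (see above).
* Correlation pruning is greedy in column order; a different column order
  can keep a different representative of a correlated group.
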