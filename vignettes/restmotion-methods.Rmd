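---
title: "restmotion: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{restmotion: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restmotion)
```

This vignette is the package's own account of what it computes and why the
open design choices were made the way they were. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The synthetic cohort: a stated world

The generator emulates resting-hand recordings from two IMUs (hand and
forearm), each with a triaxial accelerometer, gyroscope and magnetometer, at
50 Hz for 15 s (750 samples), three trials per subject. The default cohort
is 15 PD-like and 12 healthy-like subjects, with 11 of the 15 PD subjects at
Hoehn & Yahr stage 1 — i.e. without visually apparent tremor.

The tremor model is deliberately minimal:

$$s(t) = A \, e(t) \sin(2\pi f t + \varphi),$$

with `f` drawn uniformly in 3.5–7.5 Hz per subject, `φ` uniform per trial,
and `e(t)` a slow positive amplitude-modulation envelope (rectified white
noise smoothed with a one-second moving average, normalized to unit mean).
The oscillation is projected onto the three axes of each IMU by a per-IMU
random unit vector and coupled into every sensor with a fixed gain
(hand sensors 1.0, forearm 0.6, magnetometers 0.1 of their IMU's gain —
magnetometers see orientation, not acceleration, so they carry only a weak
trace of the motion; this is what lets a ranking recover the
accelerometer/gyroscope dominance observed on real data). Each axis then
receives independent Gaussian noise with standard deviation `noise_sd`
(the "noise floor", default 1 in arbitrary sensor units), and each
accelerometer z axis a gravity-like constant offset of 9.81, which the
band-pass removes.

Tremor amplitude `A` is expressed as a multiple of the noise floor:
HY-1 subjects draw from 0.2–0.6 (sub-visual), HY-2 subjects from 2–5
(clearly visible), so HY-2 amplitudes strictly dominate HY-1 within a
cohort. Healthy subjects have `A = 0` — their residual oscillation spectrum
is a free modelling choice that nothing downstream should depend on, so the
simplest (white noise through the same band-pass) is used.

What the generator does **not** emulate: biomechanical tremor dynamics
(harmonics, re-emergent tremor latency), bradykinesia, sensor drift or
calibration error, and any within-cohort age/medication structure. A green
recovery test therefore establishes that the pipeline detects an
oscillatory power asymmetry of the stated size in the stated band — not
clinical performance on real patients.

All randomness flows from one master seed through named substreams
(`derive_seed(seed, name)`, a 31-bit hash), so adding a pipeline stage never
perturbs another stage's draws, and identical seeds give byte-identical
cohorts, splits, folds and forests.

## Preprocessing

Each axis is band-pass filtered to 1–16 Hz, the per-sensor resultant
`R = √(x² + y² + z²)` is formed, and its mean subtracted. Filtering precedes
the resultant (the resultant of filtered axes is not the filtered
resultant; the narrative order of the published protocol is followed).

The filter family and order are not dictated by the protocol, so the
package uses the field's default: a 4th-order Butterworth prototype
(digital order 8 after the band transform) applied forward and backward,
giving zero phase — features computed on the filtered signal stay
time-aligned with the raw recording. Edge transients matter on 750-sample
records, so the signal is extended at both ends by an odd reflection of at
least three time constants of the slow 1 Hz edge (`3·rate/low` samples,
capped at the signal length) and the forward pass starts from the
steady-state step-response initial condition scaled by the first sample.
The design was validated against an independent DSP implementation to
10 significant digits during development; the shipped tests assert the
contract itself: pass-band gain within 5% at 8 Hz, stop-band gain below 0.1
at 0.2 Hz, and no phase shift of a band-interior tone.

The magnetometer is filtered identically to the other sensors — uniform
treatment is the only reading consistent with a single band-pass step.

## The 18 features

Per detrended resultant, in fixed report order: RMS, peak, MAV, MAVFD,
MAVSD, FMEAN, zero crossings, FPEAK, F50, F80, 3.5–7.5 Hz band power, ApEn,
FuzzyEn, variance, range, interquartile range, skewness, kurtosis. Six
sensors × 18 features = 108 per subject, named `<sensor>.<feature>`.
Choices a re-implementer must pin down:

* **Spectral estimator.** The discrete-sum definitions of FMEAN/F50/F80
  presuppose a single spectrum vector; the raw one-sided periodogram of the
  full 750-sample record (no windowing) is the simplest estimator
  consistent with them, scaled so the bins sum to the signal's mean square
  (Parseval). A Welch estimator (Hann, 50% overlap) is available via
  `power_spectrum(..., method = "welch")` for smoother spectra.
* **F50/F80 on a grid.** The defining equalities cannot hold exactly on a
  discrete grid; the package returns the first grid frequency at which
  cumulative power reaches 50% / 80% of the total — monotone (F50 ≤ F80)
  and deterministic.
* **Band power** sums bins with `3.5 ≤ f ≤ 7.5` (edges inclusive).
* **MAV windowing.** The window is the whole record (`S = N`): a single
  15-s rest trial has no event structure to window over, so MAV is the
  global mean absolute value.
* **Zero crossings** count strict sign changes between consecutive samples;
  an exactly-zero sample inherits the preceding sign; no hysteresis —
  the signal is already band-passed and detrended.
* **Quartiles** (interquartile range) use linear interpolation between
  order statistics (R's default type 7), documented so the test oracle
  matches.
* **Skewness/kurtosis** are the moment ratios `m₃/σ³` and `m₄/σ⁴`
  (kurtosis non-excess: Gaussian ≈ 3).

### Entropies

ApEn follows the classical construction: templates of length `m` and
`m + 1`, Chebyshev distance, self-matches included,
`ApEn = Φᵐ − Φᵐ⁺¹` with `Φ` the mean log match frequency. FuzzyEn differs
in three ways, all canonical: each template has its own mean removed before
the distance, the hard threshold is replaced by the membership
`exp(−(d/r)ⁿ)`, and self-matches are excluded. The published formula mixes
`N−m+1` and `N−m` denominators inconsistently; the package follows the
cited canonical construction (both phases use `N−m` templates, mean over
`j ≠ i` with denominator `N−m−1`). Both are O(N²) in C++ and are tested for
exact (1e−10) agreement with brute-force double-loop R oracles at N ≤ 100.

`(m, r)` are nowhere specified in the protocol; the package uses the
literature defaults `m = 2`, `r = 0.2 · SD` of the individual detrended
resultant (making the features scale-free), fuzzy exponent `n = 2`. A
constant signal has entropy 0 (every template matches); adding a constant
offset leaves FuzzyEn unchanged by construction.

### Degenerate inputs

On a zero-power signal the spectral quantile features (FMEAN, FPEAK, F50,
F80) have no defined value; they are returned as flagged `NA` with a
warning rather than an arbitrary number that would silently corrupt
ReliefF ranking. Amplitude and variability features are genuinely 0 there,
and entropies 0 as the limiting value.

### Trials to subjects

Features are computed per trial and averaged per subject (three trials
each) before classification, because classification operates on subjects
(27 rows). Averaging is the simplest consistent reduction; per-trial rows
remain available via `cohort_features(..., aggregate = "trial")`.

## Selection

Features are Z-score normalized once (`(x − μ)/σ`, n−1 denominator;
constant columns dropped with a warning) before both ranking and
classification — a single normalized table keeps the two stages consistent;
whether the original analysis ranked raw or normalized features is
unrecorded, and ReliefF's internal min–max scaling makes it largely
insensitive to the choice.

ReliefF uses `k = 1` nearest hit/miss, Manhattan distance on min–max scaled
features, and a deterministic pass over every row rather than random
subsampling — 27 rows make exhaustive iteration cheap and exactly
reproducible. Weight ties break by column position. By default ranking uses
the training rows only (leak-free); `rank_on = "all"` reproduces the
all-rows variant. Percentage subsets take `round(pct/100 × 108)` names,
round-half-up — forced by the protocol's own arithmetic, where the 10% step
holds 11 features — and are nested by construction.

## Classifiers

* **KNN**, `k = 3`: Euclidean distance on the Z-scored features, majority
  vote. With two classes and `k = 3` a tie is impossible; the documented
  tie rule (nearest single neighbor) exists for other `k`.
* **SVM**, polynomial kernel `(γ⟨u,v⟩ + c₀)³`, cost 1, `γ = 1/p`: solved by
  a deterministic SMO (Platt's second-choice heuristic, no random pair
  selection). `c₀` is unrecorded in the protocol; the package defaults to
  `c₀ = 1` rather than the libsvm default 0, because on centred (Z-scored)
  features the homogeneous cubic kernel is needlessly degenerate — `c₀` is
  exposed in `classifier_spec()`.
* **RF**, 120 trees, `⌊√p⌋` features per split, trees grown to purity,
  deterministic platform-independent RNG (xorshift64*). The fitted handle
  stores the training table and derived seed and regrows the forest inside
  `predict` — at n ≤ 27 this costs milliseconds, keeps the forest out of R
  serialization, and preserves the determinism contract (tested). Note
  that because column order enters the RNG stream, RF predictions are
  invariant to feature permutation only in distribution, not bitwise; the
  permutation-invariance test covers KNN/SVM/NB.
* **NB**: Gaussian ("normal") class-conditional density per feature with a
  1e−9 variance floor.

Only `K = 3`, `120 trees`, the polynomial kernel and the normal density are
fixed by the benchmarked configuration; everything else is a documented
default exposed in `classifier_spec()`.

## Evaluation protocol

The protocol reports both a ~50/50 subject split and tenfold
cross-validation without stating how they compose. The package's reading —
the only one consistent with reporting a "training accuracy" column next to
test metrics from a 13-subject test half — is:

* stratified split by subject, `ceiling(n_class/2)` per class to training
  (27 → 14/13);
* **training accuracy** = tenfold cross-validated accuracy on the training
  half, stratified folds, per-fold confusion matrices **pooled** before
  computing metrics (robust to folds that miss a class at n = 14);
* **sensitivity/specificity/precision/accuracy** = one evaluation of the
  training-half model on the held-out half, PD as the positive class.

Metrics with a zero denominator are flagged `NA`, never 0 or 1. The metric
arithmetic is tested exhaustively over every confusion matrix with at most
6 subjects.

## What the green tests establish — and what they cannot

The acceptance suite shows: the structural counts (108 = 6 × 18, 36
accelerometer features, 11 at the 10% step); exact agreement of the C++
entropies and the R ReliefF with brute-force oracles; closed-form feature
values on whole-period sinusoids within 1%; and synthetic recovery — with
every PD amplitude ≥ 3× the noise floor, each classifier's mean held-out
accuracy over 10 seeds exceeds 0.9, while with the tremor term removed
entirely it sits within 0.15 of chance over 20 seeds.

It cannot show agreement with the published clinical metric tables: the
underlying 27-subject recordings are not public, and several analysis
constants (`m`, `r`, SVM degree/cost, trial aggregation) are unrecorded, so
those numbers are not reproducible from the protocol alone. On the default
synthetic cohort — where 11 of 15 PD subjects oscillate below the noise
floor — held-out accuracies fall between chance and perfect, which is the
qualitatively expected regime, but the package makes no claim that its
synthetic difficulty matches the clinical difficulty.

## Known limitations

* The tremor model is a single amplitude-modulated line; no harmonics,
  no frequency drift within a trial.
* `split_subjects` stratifies by class only, not by HY stage, so at small
  n the HY-2 subjects can land unevenly across halves (as in any random
  split of 4 subjects).
* The SMO solver targets small-n problems (tens of rows); it is not tuned
  for large kernels.
* CSV recording files serialize at 15 significant digits; round-trips are
  identical to 1e−9 per sample, not bit-exact.
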