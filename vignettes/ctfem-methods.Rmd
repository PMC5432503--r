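---
title: "Decoding and encoding models for spatial attention in EEG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding and encoding models for spatial attention in EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`ctfem` analyses epoched multichannel EEG from visual-search experiments in
which a colour-defined target appears at one of *k* display positions. It
provides two complementary multivariate analyses of the raw (broadband)
signal:

* a **backward decoding model (BDM)** — per-timepoint linear discriminant
  classification of target position with stratified 10-fold
  cross-validation, giving a classification-accuracy time course and, via
  the covariance (Haufe) transformation, interpretable activation patterns;
* a **forward encoding model (FEM)** — a delta-basis linear encoding of *k*
  hypothetical position channels, estimated by ordinary least squares on
  training folds and inverted on held-out folds to yield single-trial
  channel responses, aligned and averaged into a **channel tuning function
  (CTF)** per time sample. Because the model is invertible, channel
  responses for positions that were never presented can be interpolated
  from the CTF and mapped back through the weights to predict their scalp
  topographies.

Classical ERP measures are included for reference: condition-balanced ERP
averaging and the N2pc contralateral-minus-ipsilateral difference at
PO7/PO8, which by construction is blind to targets on the vertical
meridian — the motivating contrast with the multivariate models.

A synthetic-data generator with fully known ground truth accompanies the
analyses so that every stage can be validated.

# The models

## Backward decoding

At each time sample, trials × electrodes amplitudes are the features. The
classifier is classic LDA: class means plus a pooled within-class
covariance, shrunk toward the scaled identity with an automatically chosen
(Ledoit–Wolf) intensity. Shrinkage matters because 23–27 electrodes against
~70 training trials per class can produce ill-conditioned covariances; with
abundant, well-conditioned data the intensity tends to zero and the
estimator reduces to ordinary LDA (the test suite cross-checks decisions
against `MASS::lda` in that regime). Assignment is the arg-max of the
discriminant score under equal priors, ties broken toward the lowest class
index.

Accuracy is computed per class in the held-out fold, then averaged over
classes, then folds — a macro average, so an imbalanced test fold cannot
drag the aggregate toward the majority class. Folds are stratified and
seeded; randomising trial-to-fold assignment also destroys any information
carried by acquisition order.

Classifier weights are not interpretable as neural sources, so topographies
are derived by multiplying the discriminant contrast with the training-data
covariance (the Haufe transformation); for a two-class LDA this equals, up
to scale, the mass-univariate class difference. Patterns are spatially
normalised (mean 0, population SD 1 across electrodes) when compared across
recordings.

## Forward encoding

For training trials with labels `l`, the design matrix `C1` (k × n₁) has
column `j` equal to the basis column of `l[j]`. The default basis is the
identity ("delta basis"): no assumption about tuning shape is imposed, so a
graded CTF in the output is a property of the data, not the basis. Weights
are the OLS solution `W = B1 C1ᵀ (C1 C1ᵀ)⁻¹` — with the delta basis, column
*p* of `W` is exactly the mean training topography of condition *p*.
Inversion on the held-out fold solves `min ‖W c − b‖` per trial (SVD-based
least squares; see *Numerical choices*). Per-condition mean responses are
circularly shifted so each condition's own channel lands on a common center
(channel 4 by convention), then averaged across conditions: the empirical
canonical CTF, repeated per time sample.

For a position between sampled positions, the canonical CTF is first made
line-symmetric about its center (averaged with its mirror image — the
simplest operator consistent with a "line symmetrical" group CTF; the exact
mirror axis is otherwise underdetermined), re-centered on each of the two
neighbouring position channels, and averaged with weights proportional to
angular proximity. Midpoint tags map to equal-weight pairs: top = (8, 1),
right = (2, 3), bottom = (4, 5), left = (6, 7), with positions numbered
clockwise from the upper right. Multiplying an interpolated response vector
with the fold-averaged weights (`coef(fem, window = c(260, 270))` when
emulating the canonical analysis window) predicts the scalp topography of a
position that was never shown. Weights are averaged over folds first, then
(when a group analysis is emulated) over subjects; the alternative orders
are not distinguishable from the published procedure and this one keeps the
single-subject object self-contained.

## Statistics

Sample-wise t tests are corrected by cluster-based permutation: contiguous
(time) or graph-connected (electrodes) samples with two-sided p below the
cluster-forming threshold and a common sign form clusters scored by their
summed t. The null is the maximal absolute cluster mass under subject-level
sign flips (one-sample) or group-label exchange (two-sample), with p-values
using the (b + 1)/(n_perm + 1) convention; an exhaustive-enumeration mode
exists for small samples and is tested against brute force. Positive and
negative clusters are formed separately and each compared to the max-|mass|
null, realising a two-tailed cluster test. Note the fixed-effects caveat
that applies to t tests on k-fold classification accuracy: such tests
support inference about the tested sample, not the population.

# The synthetic generator

Each trial with position label *p* is

```
data(t) = W_true · c_true(p) · s(t) + noise
```

* `W_true` (electrodes × channels): one smooth 2-D Gaussian bump per
  position channel, centred over posterior scalp contralateral to the
  stimulated hemifield and rotating with the position angle — a coarse
  retinotopic gradient. Bump width 0.6 head-radius units.
* `c_true(p)`: a wrapped Gaussian over the k position channels, peak 1 at
  channel *p*, width σ = 1.2 channels.
* `s(t)`: a raised-cosine envelope, zero before 180 ms, peaking at 265 ms,
  returning to zero at 600 ms — matching the rapid post-200 ms rise and the
  200–300 ms peak window of position information in this paradigm.
* noise: white Gaussian per electrode/sample (optionally spatially
  correlated over the montage, to stress-test covariance-based patterns).

Defaults emulate the eight-position design: positions at 22.5° + 45°·(j−1)
clockwise from the top (never on a midline), 96 trials per position (768
total), 27 electrodes, 250 Hz, −100..1000 ms epochs, signal amplitude 2 µV.
The noise level (4 µV per sample) was set so that peak 8-way decoding
accuracy lands near 0.30 against chance 0.125 — the effect size the method
reports at its decoding peak — and then frozen; it is the generator's only
tuned constant.

What the generator does **not** emulate: volume conduction from a
biophysical head model, temporally correlated (1/f) noise, ocular/muscle
artifacts beyond an injectable HEOG step, inter-subject variability in
`W_true`, or the two-display trial structure of the four-position
experiment. Passing tests on this generator therefore demonstrate
correctness of the estimators under a known truth, not robustness to every
property of real recordings.

## What the CTF width does and does not estimate

A subtle and, we think, underappreciated point follows from the delta-basis
algebra. With noise-free data the per-class mean topographies separate the
k conditions perfectly, so model inversion returns the identity: the
canonical CTF is a *delta*, regardless of the generative tuning width. The
graded CTF observed at realistic noise arises because noise in the
estimated weights attenuates the inverse toward the Gram structure of the
condition topographies — approximately `E[CTF] ∝ (G + λI)⁻¹ G e_p` with `G`
the condition-topography Gram matrix and `λ` growing with noise. Its fitted
width therefore sweeps from 0 (no noise) to roughly √2·σ convolved with the
spatial-overlap structure (heavy noise), crossing the generative σ only at
one knife-edge noise level. At the frozen default noise the fitted circular
Gaussian width is ≈1.4–1.5 channels against a generative σ of 1.2 — a
20–25% overestimate, stable across seeds. The package reports the CTF as an
*empirical description of position tuning in the data*, which is exactly
how it is used downstream (interpolation and topography reconstruction are
insensitive to this attenuation); it should not be read as a calibrated
estimator of an underlying tuning width. The test suite asserts the
noise-free delta identity exactly and the graded shape at default noise.

# Tunable parameters

| parameter | default | units | notes |
|---|---|---|---|
| `K` folds | 10 | — | stratified, seeded; every class in every training split |
| shrinkage | `"auto"` | — | Ledoit–Wolf toward scaled identity; 0 = plain pooled covariance |
| cluster_alpha | 0.05 | — | two-sided cluster-forming threshold |
| n_perm | 1000 | — | permutations; (b+1)/(n+1) p-values |
| baseline window | −100..0 | ms | −200..−100 ms for the two-display design |
| high-pass | 0.1 (transition 0.1) | Hz | Hamming sinc FIR, −6 dB at 0.05 Hz, 33 s kernel at 500 Hz, zero-phase |
| step detector | 100 / 50 / 0–500 / 25 | ms, ms, ms, µV | half-window mean difference |
| encoding center | 4 | channel | alignment target |
| analysis window | 260–270 | ms | weight window for reconstruction |
| display rate | 32 | Hz | spline smoothing grid, anchored at the peak |

# Numerical choices

* **OLS solves** in the encoding model use SVD-based least squares with a
  relative singular-value tolerance of 1e-10. The normal equations would
  square the condition number of the weight matrix, which reaches ~10⁶ for
  realistic overlapping-bump topographies; the SVD route keeps the
  noise-free round trip exact to ~1e-10 and turns genuine rank deficiency
  into an informative error.
* **Degenerate covariances** (e.g. noise-free fixtures) receive a
  proportional ridge after shrinkage so the discriminant stays defined; the
  arg-max decision is unaffected.
* **Zero-variance samples** in t tests yield ±Inf t (flagged by a warning)
  with p = 0 when the mean differs from the null, and t = 0 when it does
  not — so all-zero background channels cluster as "no evidence", not NaN.
* **Ties**: classifier scores break toward the lowest class index; peak
  finding returns the earliest sample.
* **Display smoothing** resamples to 32 Hz on a grid anchored at the peak
  sample (the peak is a retained point, so its height is not diluted) and
  interpolates a natural spline back to the original axis; the result is
  flagged display-only and statistics always use the raw series.
* **Step detector attenuation**: with a 100 ms window sliding in 50 ms
  steps, a step whose onset is misaligned with the half-window grid is
  attenuated by up to a factor 2 in the half-window mean difference; only
  amplitudes ≥ 2× threshold are guaranteed to be flagged at arbitrary
  onsets (grid-aligned onsets are detected at full amplitude). The
  "amplitude fluctuation" is operationalised as the absolute difference of
  half-window means, the standard ERP-lab step function.
* The filter length rule is 3.3/transition-bandwidth (Hamming), rounded to
  odd; for epoched data the kernel is clamped to the data length with a
  warning.

# Design choices that were genuinely open

* **Permutation unit** for decoding-accuracy statistics: subjects (as in
  group analyses) rather than trials; the pipeline's single-recording
  `stats` command uses folds as exchangeable units and says so in its
  output.
* **Haufe covariance**: computed from the training data of the same fold,
  keeping the transform independent of test data.
* **Multi-class patterns** are produced per pairwise contrast or
  class-vs-rest; published two-class patterns correspond to the pairwise
  form.
* **Normalisation convention**: population (divide-by-n) SD; affine
  invariance holds under either convention.
* **Ground truth for never-presented positions**: the generative-model
  extension `W_true · c_true(angle)` with the tuning profile evaluated at
  the continuous angle. The alternative — moving the cortical bump itself —
  produces a pattern partly outside the span of the sampled topographies;
  reconstructions correlate ~0.99 with the former and ~0.9 with the latter
  at default noise, and the package exposes both
  (`truth$topography`, `truth$bump_topography`).
* **EEGLAB import** is not implemented (binary MATLAB container); the
  native array-plus-JSON-sidecar container is the supported interchange
  format, and an external-cleaning hook accepts data cleaned elsewhere
  (e.g. ICA blink removal, which this package deliberately does not
  re-implement).

# Problem sizes used by the test suite

Unit tests run on reduced designs (typically 8–40 trials per position,
−100..500 ms epochs) chosen to exercise every code path in seconds. The
end-to-end validation uses the full default design (768 trials, 276
samples) for chance recovery; 8 simulated subjects for reconstruction
validity and tuning statistics; 500 null datasets × 200 permutations for
the family-wise-error calibration (at α = 0.05, 200 permutations resolve
the relevant tail adequately; the default for real analyses remains 1000);
and exhaustive sign-flip enumeration at n = 5 against a brute-force oracle.

# Known limitations

* Fixed-effects inference for within-subject decoding statistics (see
  above); prevalence-style population inference is out of scope.
* No temporal generalisation matrices, no time–frequency (alpha-band)
  CTFs, no non-delta basis fitting beyond accepting a custom basis
  verbatim, no jackknife latencies.
* The CTF width caveat above applies to any delta-basis inversion, not
  just this implementation.
* Montage coordinates are an idealised 2-D projection adequate for
  adjacency and smooth ground-truth construction, not for source
  modelling.
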