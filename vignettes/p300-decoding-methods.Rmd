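---
title: "Methods: single-trial P300 decoding with a separable CNN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-trial P300 decoding with a separable CNN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A nine-target P300 speller flashes nine stimuli once per trial in random
order at a 175 ms stimulus-onset asynchrony (100 ms flash + 75 ms gap). The
attended stimulus evokes a P300, a positive event-related potential peaking
roughly 400--500 ms after its flash. Decoding a trial means scoring the nine
stimulus-locked EEG epochs and selecting the stimulus with the highest
score. Under augmented-reality (AR) presentation the P300 is smaller and
roughly 50 ms later than under a computer screen (CS), which makes
*single-trial* (non-averaged) decoding harder and motivates a lightweight
separable convolutional classifier over the classical averaged pipelines.

This package provides the whole chain: a seeded synthetic session generator,
the standard preprocessing, the separable CNN and a standard-CNN comparator,
four classical baselines, and the evaluation harness (per-run accuracy, AUC,
Wolpaw information transfer rate, paired t-tests, one-way ANOVA).

## The synthetic session generator

No public recordings exist for this protocol, so the package simulates it.
The stated world of the generator (defaults of `sim_params()`):

* **Protocol** — 10 runs x 9 blocks x 5 trials x 9 flashes (`make_schedule()`),
  SOA 175 ms, 2 s preparation and 1.5 s target lock per trial, 600 ms tail
  after the last flash so a full epoch always fits. Block `b` cues stimulus
  `b`: the cue sweeps the stimuli in fixed order, one per block.
* **ERP template** — a one-cycle raised-cosine positive pulse, 300 ms wide,
  added at every *target* flash only. Peak latency is drawn once per session
  from N(482.47, 3) ms in AR and N(434.53, 3) ms in CS — the across-session
  means and spread of the published per-participant latencies shipped in
  `ref_latency_table()` — plus per-flash jitter of SD 20 ms, a typical
  single-trial latency variability. Only the peak latency and the AR/CS
  amplitude ordering are empirically constrained; the pulse shape itself is
  a modeling choice.
* **Amplitude and topography** — 5 µV at the topography maximum (a typical
  P300 magnitude; no published value exists for this dataset), scaled by a
  Gaussian spatial bump centred between Pz and Oz. The AR amplitude is
  scaled by `ar_amplitude_scale = 0.7`; the published evidence is only
  qualitative ("lower in AR"), so any value in (0.5, 0.9) is defensible and
  the parameter is configurable.
* **Noise** — per channel: 1/f pink noise (6 µV RMS), a 10 Hz alpha
  sinusoid with random phase (3 µV RMS), and white noise (2 µV RMS).
  These magnitudes give realistic single-digit single-trial SNR.
* **Channels** — 30 scalp channels of the 10--20 system plus two noise-only
  mastoids (A1/A2), so the channel-dropping step operates on real input.

What the generator does *not* model: volume-conducted forward-model
topographies, eye-blink/EMG artifacts, drifting electrode impedances,
non-stationary alpha power, or between-participant variability beyond the
latency draw. A green recovery test therefore establishes that the pipeline
is correct and well-calibrated on data with the stated statistical
structure, not that it reproduces human performance numbers.

The test suite's "high SNR" world divides the three noise RMS levels by four
and halves the per-flash jitter; it was fixed before any test was run and is
defined in one place (`tests/testthat/helper-fixtures.R`).

## Preprocessing

`preprocess_session()` applies, in order: channel dropping (A1/A2),
a zero-phase 0.1--12 Hz bandpass, 600 ms epoch extraction time-locked to
each flash, and decimation by 3 to 200 samples per epoch (at 1 kHz). Epoch
windows overlap (SOA 175 ms < 600 ms) and are extracted independently.
No baseline correction and no artifact rejection are applied.

Numerical choices:

* **Filter realization.** The bandpass is a cascade of a 2nd-order
  Butterworth high-pass (0.1 Hz) and low-pass (12 Hz), each applied
  forward-backward. A direct 8-pole transfer-function bandpass with these
  edges is numerically unstable at fs = 1000 Hz (the 0.1 Hz poles sit at
  machine-precision distance from z = 1); the biquad cascade is exact and
  stable, and its squared magnitude response is the intended 4th-order
  zero-phase characteristic.
* **Edge handling.** Forward-backward filtering uses even-reflection padding
  (three high-pass time constants long, capped at the signal length) plus
  steady-state initial conditions matched to the first sample. Odd
  (point-mirrored) reflection — the scipy default — injects a `2*x[end]` DC
  offset into the pad, which excites the slow high-pass pole and leaves a
  multi-second transient inside the signal; even reflection carries no such
  offset. With this choice a 30 Hz probe tone is attenuated below 4% RMS
  end to end, against 27% for the scipy-default scheme.
* **Decimation** keeps every 3rd sample with no extra anti-alias filter:
  the 12 Hz low-pass already bounds the spectrum far below the 166.7 Hz
  post-decimation Nyquist.
* **Multi-averaging** (`average_repetitions()`) averages the first k
  *epochs* of each (run, block, stimulus) before scoring — the standard
  P300 practice — rather than averaging classifier scores.

## The separable CNN

Input epochs are 200 x 30 (time x channels). The layer stack is
BatchNorm → depthwise Conv1D (one kernel of size 10 per channel, stride 6,
padding 4, output 34 x 30) → BatchNorm → pointwise Conv1D (four size-1
kernels, output 34 x 4) → Tanh → Flatten (136) → Dense (136 → 1, with bias)
→ Sigmoid. The standard-CNN comparator replaces the two convolution stages
with a single ordinary Conv1D (30 in, 4 out, size 10, stride 6, padding 4)
and drops the second BatchNorm. With size-1 output per epoch, the sigmoid
value is the target probability; nine epoch scores per trial feed an argmax
(ties resolve to the lowest stimulus index).

Design points that the architecture description leaves open, resolved here:

* The 136 → 1 transition requires a fully connected layer; it carries a bias.
* Both "normalization layers" are batch normalization: batch statistics in
  training, running averages (momentum 0.1) at inference.
* Convolution stages carry biases.
* Per-epoch input standardization is left entirely to the leading BatchNorm.

**Training recipe** (`train_hyper()`, unconstrained by the source
architecture): Adam (lr 1e-3, β = 0.9/0.999), batch size 64, at most 200
epochs, early stopping on a held-out 20% validation split (patience 20,
best weights restored), binary cross-entropy with the positive class
weighted by the non-target:target ratio (8 under the default protocol).
All randomness — initialization (uniform ±1/sqrt(fan-in)), the validation
split, batch order — derives from one seed, and identical inputs reproduce
the fitted network bit for bit.

**Cost model.** `separable_cost()` evaluates the closed-form single-layer
cost expressions `C_sep = h(H1-h+1) + n(H1-h+1)` and `C = nh(H1-h+1)`,
whose ratio is identically `1/n + 1/h`. These formulas use the stride-1,
no-padding output length even though the implemented layers use stride 6
and padding 4; they are implemented exactly as stated, not "corrected",
because they are a printed result being reproduced.

**Implementation.** Layers are hand-written in vectorized R with a
channels-first internal layout; the strided depthwise convolution runs as
per-channel banded-matrix GEMMs. Gradients of every layer are verified
against central finite differences, and the forward pass against
brute-force nested-loop convolution oracles kept in the test suite.

## Classical baselines

All four operate on the flattened 6000-dimensional epoch vector with
per-feature z-scoring fitted on training data only (stored in the scorer).

* **LDA** — Fisher discriminant with the pooled covariance shrunk toward a
  scaled identity; the shrinkage intensity is a Ledoit-Wolf-style analytic
  estimate computed entirely from the n x n Gram matrix, and the inverse is
  applied through the Woodbury identity (d = 6000 ≫ n).
* **BLDA** — Bayesian linear regression of ±1-coded labels with an
  isotropic Gaussian prior (bias excluded via centering); prior and noise
  precisions are fitted by MacKay evidence maximization in the sample space
  through a thin SVD (tolerance 1e-4, ≤100 iterations; non-convergence is
  returned flagged with a warning).
* **SWLDA** — forward-backward stepwise OLS on coded labels: enter the
  smallest partial-F p-value below 0.1 (ties to the lowest feature index),
  remove coefficients with p above 0.15, every entry or removal counts one
  step, 60 steps maximum (hence ≤60 active features).
* **Linear SVM** — C = 1, L1 hinge, solved by dual coordinate descent with
  the bias as an augmented unit feature (liblinear formulation). The test
  suite checks the decision values against an independent quadratic-program
  solution of the same dual.

## Evaluation

`crossval()` partitions *trials* (never single epochs — the nine epochs of
a trial share a fold) into five folds stratified over runs, fits the model
factory per fold, scores held-out epochs, decodes, and aggregates per-run
accuracies, the pooled AUC (exact rank/pair counting, ties half), and the
ITR.

**Selection time for the ITR.** The Wolpaw rate needs a time per selection,
which the protocol description never states. The default T = 2.0 s is the
flash sequence of one trial (9 x 175 ms) plus the 425 ms needed to complete
the final 600 ms epoch, excluding preparation and lock time; it is a
configurable parameter. Per-participant ITRs computed at T = 2.0 s from the
shipped reference accuracy table average 58.01 bits/min, within 0.2% of the
published 57.90, which is what fixed the default.

**ITR aggregation** is per participant first, then averaged (the pooled
accuracy would give ≈57.1 by Jensen's inequality). **p-values** are
reported raw, with no multiple-comparison correction, matching the
benchmark convention.

**Reference tables.** The published benchmark per-run accuracies
(`ref_accuracy_table()`) contain one internal inconsistency: participant
P7's printed mean (93.33) is not the mean of its printed run values
(92.22). The fixture therefore stores the printed means as their own column
(`mean_printed`); layout arithmetic is tested against recomputed values
where they are self-consistent (P1) and against the printed means where the
published summary is the ground truth (grand mean, ITR).

## Known limitations

* Synthetic sessions cannot validate absolute human-level accuracy numbers,
  only pipeline correctness, calibration, and qualitative orderings.
* The SVM's bias is weakly regularized (augmented-feature formulation);
  with 6000 standardized features this is immaterial.
* EDF/BrainVision import is out of scope; sessions interchange via the
  documented HDF5 container and CSV exports.
* Cross-participant training is supported only in the sense that any epoch
  set can be pooled; no dedicated transfer-learning split ships with the
  package.
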