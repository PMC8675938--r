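---
title: "Scoring CAD risk from rest seismocardiography and gyrocardiography"
author: "scgrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring CAD risk from rest seismocardiography and gyrocardiography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(scgrisk)
```

## The measurement and the model

A sternal inertial sensor records the chest wall's reaction to the beating
heart: linear acceleration (the seismocardiogram, SCG, three axes) and
angular velocity (the gyrocardiogram, GCG, three axes), alongside one ECG
lead used purely as a timing reference. The working hypothesis of this
pipeline is that coronary artery disease alters the *time-frequency
content* of these cardiac-cycle waveforms below 40 Hz, and that a
convolutional classifier can learn that signature from per-cycle
time-frequency images without any hand-crafted fiducial features.

The pipeline is a fixed chain:
preprocessing → ECG-anchored segmentation → synchrosqueezed
time-frequency features → per-channel 1D CNNs → leave-one-subject-out
(LOSO) evaluation with ensemble fusion. Each stage is an exported
function, so every intermediate object can be inspected.

## Stages, parameters, and why they have these defaults

### Preprocessing (`preprocess_recording`)

* **High-pass**: zero-phase Butterworth, order 5, cutoff 0.5 Hz —
  removes baseline wander (respiration, posture drift) while leaving all
  cardiac frequencies untouched. At 0.5 Hz normalized cutoffs the
  single transfer-function realization numerically loses its DC zero, so
  the filter runs as a cascade of second-order sections; each pass starts
  in steady state for the first padded sample, which makes DC rejection
  exact. Zero-phase (forward–backward) filtering matters because Q-point
  timing anchors everything downstream.
* **Normalization**: demean, then divide by the maximum absolute value —
  every channel lives in [−1, 1], removing inter-subject amplitude
  confounds (sensor coupling, chest anatomy) before any learning.
* **Decimation** to 250 Hz: order-8 Chebyshev type-I low-pass applied
  zero-phase, then every 4th sample. Ripple 0.05 dB and cutoff 0.8 × the
  output Nyquist are the conventional decimation defaults; the analysis
  band ends at 40 Hz, far below the 100 Hz filter edge. The order of
  operations is filter → normalize → downsample; a final rescale
  re-establishes max |x| = 1 exactly at 250 Hz so the output contract
  holds regardless of the order's small numerical effects.
* The ECG passes through the identical chain so its sample indices stay
  aligned with the motion channels. Only its timing is used downstream,
  which normalization cannot disturb.

### Segmentation (`annotate_beats`, `segment_cycles`, `build_series`)

* **R detection** is Pan–Tompkins: 5–15 Hz band-pass, five-point
  derivative, squaring, 150 ms moving-window integration, adaptive dual
  thresholds with a 200 ms refractory period and RR search-back at half
  threshold. Candidates must dominate a ±100 ms neighbourhood of the
  integrated signal, which suppresses noise riblets on the QRS apex.
  Detections are refined to the raw-ECG maximum within ±50 ms.
* **Q location**: the ECG minimum in the 60 ms window ending at each R —
  the standard morphological definition; the synthetic generator's known
  30 ms Q–R offset validates it to ±4 ms.
* **Gating**: beats implying Q-to-Q intervals outside 0.3–2.0 s are
  rejected. This guards the interpolator against missed or false beats.
* Cycles are **half-open** Q-to-Q slices (concatenating them
  reconstructs the signal exactly), linearly interpolated to 250 samples
  each, and grouped into **non-overlapping** runs of 10 consecutive
  cycles (2,500 samples). Non-overlap avoids double-counting cycles in
  evaluation; a trailing remainder under 10 cycles is discarded.

### Time-frequency features (`sst_transform`, `extract_features`)

* The **synchrosqueezing transform** computes an analytic-Morlet CWT
  (center frequency ω₀ = 6, the conventional choice) on 178 log-spaced
  scales from 0.5 Hz to the 125 Hz Nyquist, estimates each coefficient's
  instantaneous frequency from the phase transform
  Im[(∂W/∂t)/W]/2π, and reallocates coefficient magnitude to the nearest
  frequency row. Reallocation is the point: a pure tone that the plain
  scalogram smears across scales collapses into a ±2 Hz band (the test
  suite checks ≥ 70 % of total magnitude lands there, and that the CWT is
  strictly less concentrated). Coefficients below 10⁻⁸ of the plane
  maximum are left unallocated — the phase of numerical noise is
  meaningless.
* The 178-row count is a *default, not a contract*: the per-cycle plane
  is standardized by linear re-gridding of the ≤ 40 Hz band onto exactly
  150 uniform rows, so downstream shapes are independent of the scale
  grid. Frequencies above 40 Hz are discarded — the discriminative
  content is assumed below 40 Hz, and truncation removes broadband noise.
* Each 150 × 250 per-cycle matrix is reduced by **non-overlapping block
  means** over 5 rows × 10 columns to 30 × 25. Overlapping windows would
  not change the dimensions, so only block averaging is consistent with
  the 150→30 and 250→25 reduction. Each reduced matrix is min–max
  rescaled to [0, 1] **per image** (an all-constant matrix maps to
  zeros). Per-image scaling removes any residual amplitude confound
  between subjects and channels; it is the most consequential unstated
  choice in this design, and it is deliberately the most conservative
  one. Flattening is row-major; with consistent use the orientation is
  irrelevant to the CNN, but it is fixed for reproducibility.

### The per-channel classifier (`cnn_spec`, `train_channel`)

The reference architecture: three convolutional blocks (filters
32/16/16, kernel 10, "same" padding, ReLU, max-pool 2; batch
normalization *after* the ReLU in block 1 — taken literally, though
pre-activation placement is more common; dropout in blocks 2 and 3),
flatten, two 1,000-unit fully connected ReLU layers with dropout 0.5, and
a 2-unit softmax. "Same" padding lets the 750-sample input halve cleanly:
750 → 375 → 187 → 93.

Unstated training constants use the field's defaults, all exposed in
`cnn_spec()`: convolutional dropout 0.25, Adam learning rate 10⁻³, batch
size 32. The loss is 2-class softmax cross-entropy (identical to binary
cross-entropy for a 2-unit output). Training runs a fixed number of
epochs (default 100); after each epoch validation accuracy is recorded
and the returned weights are those of the best validation epoch,
earliest on ties. No class reweighting is applied by default. Everything
(shuffling, dropout, initialization) draws from R's RNG, so
(data, spec, seed) reproduces a training run bitwise.

The implementation is the package's own: im2col + GEMM convolutions and
the full training loop in compiled code, gradients verified against
finite differences in the test suite, and a capacity check confirming
the reference network can memorize 50 random vectors to training loss
< 0.05.

### Evaluation (`loso_run`, `compute_metrics`, `compare_models`)

* **LOSO**: each subject is held out in turn; the other subjects' cycles
  train six channel models. The inner 80/20 train/validation split is at
  the **subject level**, stratified by class — a cycle-level split would
  leak within-subject correlation into validation and overstate
  validation accuracy.
* **Fold balancing** (`balance_train = TRUE`): holding one subject out
  of a balanced cohort necessarily leaves the opposite class
  over-represented by one. At desk scale (6–10 subjects per class) that
  prior shift alone pushes every held-out subject's risk toward the
  majority class, systematically anti-ranking the cohort under the null.
  Each fold therefore drops random subjects of the larger class until
  its training pool is class-balanced — a label-agnostic operation with
  respect to the held-out subject. At a clinical cohort scale (hundreds
  of subjects) the correction is negligible.
* **Aggregation**: a subject's channel risk is the arithmetic mean of
  its per-cycle probabilities; fusion is the arithmetic mean across
  channels (all six, the three SCG, or the three GCG). The mean is the
  maximum-entropy choice and consistent with the fusion rule.
* **Hygiene**: cohorts with byte-identical recordings are rejected
  (md5), and each fold asserts that the held-out subject's
  feature-vector fingerprints are disjoint from its training and
  validation data.
* **Metrics**: AUC by rank method with DeLong 95% CI; confusion-matrix
  metrics at the 0.5 risk threshold with Wilson 95% CIs; discrimination
  slope = mean(risk | CAD) − mean(risk | non-CAD). Model pairs are
  compared with the paired DeLong test; a model compared with itself
  returns p = 1 by convention (the paired difference is degenerate).
  ROC direction is fixed (non-CAD = controls), so a worse-than-chance
  model honestly reports AUC < 0.5 rather than being flipped.

## The synthetic cohort: what it does and does not emulate

`synth_spec()` defines a two-class cohort. Per subject: inter-beat
intervals are i.i.d. Gaussian, mean 60/`hr_bpm` (default 70 bpm) and SD
`hr_sd_bpm`/`hr_bpm` of the mean (default 5 bpm), truncated at ±3 SD —
the simplest heart-rate-variability model that exercises the cycle
interpolation. The ECG cycle is a fixed template (Gaussian Q dip,
dominant R peak 30 ms later, S dip, broad T wave) so ground-truth Q and R
times are known exactly (`attr(rec, "truth")`). Each SCG/GCG channel
repeats a template of three Gabor atoms (Gaussian-windowed cosines at
fixed fractions of the cycle, frequencies 6–28 Hz) with per-cycle
amplitude jitter; the CAD class shifts each channel's second atom down by
10 × `separation` Hz and raises its amplitude by 40 × `separation` %.
Baseline wander is a sinusoid below 0.5 Hz (default 0.2 Hz, amplitude
0.3) and sensor noise is white (default SD 0.05 of template amplitude) —
the wander sits strictly below the high-pass cutoff, and all class
information sits strictly inside the ≤ 40 Hz analysis band, by
construction.

What passing tests on this cohort **show**: the pipeline's plumbing is
correct end to end — detectable beats are found, cycles align, the SST
features expose sub-40 Hz spectral differences at the right frequency
rows, the classifiers learn them, LOSO produces honest out-of-subject
estimates, and a cohort with no class difference yields chance-level
AUC. What they **do not show**: anything about real CAD physiology. The
generator has no MC/AO/AC/MO fiducial morphology, no respiration
modulation, no inter-subject anatomical variability beyond amplitude
jitter, and its class separation is a free parameter, not a clinical
claim.

## Problem sizes

The package's end-to-end experiments (acceptance tests and
`scripts/acceptance.R`) use 6 subjects per class, 30 s recordings, and a
narrowed CNN — `cnn_spec(filters = c(8, 8, 8), fc_units = c(128, 128))`,
the reference topology at reduced width — trained for 20 epochs
(5 for the zero-separation null, which only needs to demonstrate the
absence of signal). These sizes were chosen by compute budget: a
12-subject LOSO trains 72 networks, and at single-core BLAS throughput
the narrowed width keeps the whole experiment under ~10 minutes while
leaving the learning problem unchanged in kind. The full-width reference
architecture is exercised directly in the model-module tests
(memorization capacity, separability, gradient checks).

## Numerical choices and degenerate inputs

* Filter edge handling: reflect padding of 3 × (order + 1) samples plus
  steady-state initialization per pass. Edge transients of the 0.5 Hz
  filter still span a few seconds; tests assess zero-phase symmetry and
  idempotence away from the ends.
* All-zero or constant signals: normalization returns zeros; an
  all-constant reduced image maps to all zeros; an all-zero series gives
  an all-zero SST plane.
* Max-pooling ties keep the earliest position; best-epoch ties keep the
  earliest epoch — both deterministic.
* Cycle interpolation preserves endpoints exactly; a 250-sample cycle
  passes through unchanged.
* WFDB and EDF round-trips are exact to one least-significant bit of
  their 16-bit scaling; CSV is lossless.

## Known limitations

* The clinical performance of the method cannot be assessed here: no
  real recordings are distributed, and synthetic results say nothing
  about CAD discrimination in patients.
* The SST is magnitude-reallocated and not invertible; no alternative
  time-frequency transforms are provided.
* Beat detection assumes a reasonably clean single-lead ECG; recordings
  whose ECG is unusable are outside scope (the reference protocol
  excluded them manually).
* Artifact/motion-burst rejection is not implemented.
* EDF support is plain EDF (not EDF+ annotations); WFDB support is
  format 16 only.
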