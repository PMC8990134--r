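---
title: "Methods: decoding hindlimb kinematics from intraspinal LFP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decoding hindlimb kinematics from intraspinal LFP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

During treadmill locomotion, multichannel local field potentials (LFP)
recorded from the dorsal and lateral columns of the spinal cord carry
information about ongoing hindlimb movement. `lfpdecode` implements an
offline pipeline that turns an 8-channel intraspinal LFP record (500 Hz)
paired with six hindlimb joint angles (hip/knee/ankle of each leg, 50 Hz)
into: (i) decoded joint-angle trajectories via a 3D convolutional network
with linear baselines, (ii) gait-locked ERD/ERS time-frequency maps,
(iii) mutual-information summaries per frequency band and electrode, and
(iv) a cadence band-power comparison. Because no public recording of this
kind is deposited, the package ships a synthetic-session generator with known
ground truth; every quantitative claim the test suite makes is a
parameter-recovery statement about that stated world, not a reproduction of
in-vivo numbers.

## Feature extraction

The preprocessing chain is:

1. **Line-noise removal** — 4th-order Butterworth band-stop filters at
   50/100/150 Hz. The published description fixes order and centre
   frequency only; we use a ±2 Hz stop width.
2. **Band bank** — 4th-order Butterworth band-pass filters into
   δ (0.5–4 Hz), θ (6–12 Hz), β (15–30 Hz), γ (40–80 Hz),
   high-γ (80–120 Hz), ripple (150–210 Hz).
3. **Envelopes** — full-wave rectification, 4 Hz 4th-order Butterworth
   low-pass, resampling to 10 Hz. Because the 4 Hz low-pass is itself an
   anti-alias filter for a 10 Hz grid, resampling reduces to sampling the
   filtered series at the grid times (the centres of the ALFP windows), so
   all feature series share one time base.
4. **ALFP** — the windowed average amplitude of the broadband LFP, 200 ms
   windows stepped by 100 ms. The source description ("average of the LFP
   signal") is ambiguous about rectification; the raw LFP is near zero-mean,
   so a signed mean would be ≈ 0 and carry no amplitude information — we
   average the rectified signal.
5. **Lagged tensors** — at each 10 Hz step, a channel × lag × feature array
   (8 × 10 × 7: ten 100 ms lags of six band envelopes plus the ALFP).
   Time points without a full lag history are dropped.

All filters are applied forward–backward (zero phase). The analyses here are
offline, and gait-locked averages would be systematically shifted by a causal
filter's group delay; whether the original analysis filtered causally is not
stated. The effective order therefore doubles, which the frequency-response
tests account for (the −3 dB points quoted are those of the designed,
single-pass response).

No IIR-design facility exists in the dependency stack available to this
package, so Butterworth design (zero–pole–gain prototype, band transforms,
bilinear transform, second-order sections) is implemented in `butter_sos()`
and the SOS filter in C++. It is validated by frequency-response oracles in
the test suite.

## The decoder

One network per joint maps the 8 × 10 × 7 tensor to a scalar angle:
3D convolution (stride 1) → ReLU → 2 × 2 × 2 max-pool (stride 1) → flatten →
one hidden fully connected layer (ReLU) → linear output. Training minimizes
mean squared error plus an L2 weight penalty (coefficient 0.3) with SGD,
momentum 0.75, mini-batches of 128, 10 epochs.

Design points the published description leaves open, and our choices:

* **Padding.** A 7 × 6 × 8 filter cannot slide validly over an 8 × 10 × 7
  input followed by 2 × 2 × 2 pooling; we use same-size zero padding for
  both convolution and pooling, which keeps the printed filter and pool
  sizes usable verbatim and preserves 8 × 10 × 7 maps.
* **Hidden width and learning rate** (unstated): defaults 64 and 0.01.
* **Output-layer initialization.** The read-out weights start at zero, so
  the network begins as the training-fold mean predictor. With a random
  read-out, 10-epoch SGDM training at this scale is bimodal — it either
  converges or lingers at a plateau depending on the seed; the zero
  initialization removes the unstable early phase without changing the
  architecture or regime.
* **Normalization.** Features are z-scored per (channel, feature) and the
  target z-scored, using training-fold statistics only (leakage-safe; a test
  corrupts the test fold and verifies unchanged training artifacts).
* **One network per joint**, following the single-output description.

The implementation is single-precision C++; the stride-1 same-padded
convolution is realized as a dense operator built from the filter weights, so
forward and backward passes are plain GEMMs. A brute-force R forward pass
serves as an independent oracle in the tests.

**Desk-scale configurations.** The published capacity (70 filters, 64 hidden
units) trains in minutes per network on a single CPU, which would put the
recovery experiments far beyond the test-time budget. Recovery tests and the
acceptance suite therefore run the identical architecture and training
regime at reduced capacity (4 filters, 32 hidden units). `cnn_config()`
defaults remain the published values.

## Evaluation

`r_squared()` is the coefficient of determination in percent. Threefold
cross-validation uses **contiguous temporal blocks**: lagged features overlap
in time, and shuffled folds would leak test information into training.
Baselines are PLS1 (NIPALS; no PLS implementation exists in the dependency
stack, so it is implemented here and tested against a least-squares
equivalence oracle) and Lasso (glmnet), each with hyperparameters chosen by
an inner contiguous 3-fold CV on training data only.

## Mutual information

`mutual_information()` is an adaptive-partitioning (Darbellay–Vajda)
estimator: inputs are rank-transformed; the unit square is recursively split
into four equal quadrants while a chi-square test (α = 0.05, 3 df) rejects
uniformity of the quadrant counts and at least 8 points per prospective
quadrant remain; MI is summed over final cells, in bits, floored at zero.
On bivariate Gaussians (n = 50,000) the estimator lands within 0.01 bits of
the closed form −½·log₂(1−ρ²) for ρ up to 0.9.

## ERD/ERS maps and cadence analysis

Gait cycles come from the generator's ground-truth phase when present;
otherwise onsets are local maxima of the (low-passed) hip angle — the event
definition is not prescribed by the source, and hip extension peaks are
robust on periodic gait. Envelope samples are assigned to 100 phase bins;
the percent change of each bin mean against the cycle mean is the ERD/ERS
quantity (positive = synchronization). Bin percent-changes average to zero
by construction.

The cadence analysis groups sessions below 0.67 and above 0.73 steps/s
(sessions between are excluded), computes each session's mean band envelope
during movement (samples inside detected gait cycles), and compares groups
per band with a Welch t-test — chosen because session counts are small (six
per group) and group variances need not match.

## The synthetic world

`generate_session()` emulates the statistical structure the analyses assume:

* **Kinematics** — each joint is a truncated Fourier series of the gait
  phase φ(t) = 2π·cadence·t (default two harmonics; real joint traces are
  periodic but non-sinusoidal, which also means a linear decoder cannot be
  exactly optimal). The right leg lags the left by π (alternating gait).
  Default cadence 0.72 steps/s, within the 0.59–0.8 range of slow treadmill
  walking; baseline angles and amplitudes are in the realistic 80–130°
  range.
* **LFP** — per channel, a sum over the six bands of band-limited Gaussian
  noise multiplied by the gain 1 + m·cos(φ − ψ) (the simplest multiplicative
  coupling that yields gait-locked ERD/ERS with a closed-form cycle-averaged
  envelope), plus 50/100/150 Hz mains sinusoids, pink (1/f, FFT-shaped)
  background and white sensor noise. Base band amplitudes fall off with
  frequency as LFP spectra do. The phase is upsampled to the neural grid by
  linear interpolation (it is smooth and slow).
* **Cadence linkage** — the θ-band base amplitude scales linearly with
  cadence about 0.70 steps/s (coefficient 2 per steps/s, i.e. roughly +30%
  between the lower and higher cadence groups), so the effect the cadence
  analysis must detect is genuinely present in the stated world.
* **Determinism** — all draws happen under the session seed; identical
  configurations are bitwise identical.

No quantitative SNR or modulation depth of the real recordings is published;
the defaults (m = 0.5, white/pink noise at ~30% of the slow-band amplitude)
were chosen once for testability, not fidelity. What a green test
establishes is therefore that *the pipeline recovers known structure of this
class*; it says nothing about decoding accuracy on real spinal recordings,
and features of real data — nonstationarity, movement artifacts, electrode
drift, cross-channel correlated noise — are deliberately absent.

## Numerical choices and degenerate inputs

* Zero-phase filtering uses odd-extension padding with steady-state initial
  conditions per biquad; second-order sections keep the narrow low-frequency
  designs (δ at fs = 500 Hz) well conditioned.
* `r_squared()` raises an explicit error for a constant measured series
  (the denominator of the score is zero).
* `mutual_information()` returns 0 for constant inputs; ranks use average
  ties.
* Envelope values are clamped at zero (the zero-phase low-pass can
  marginally undershoot).
* Sessions shorter than one 200 ms window, misaligned feature series,
  unknown subset labels, band edges at or above Nyquist, and channel maps
  inconsistent with the neural array all raise informative errors.

## Known limitations

* The container format is JSON (17 significant digits, exact double round
  trip) rather than HDF5: no HDF5 bindings exist in the dependency stack
  this package may assume. The schema mirrors the intended hierarchical
  layout and the round trip is bitwise.
* The CNN is a faithful but compact re-implementation; it does not aim at
  state-of-the-art accuracy, hyperparameter search, or deeper structures.
* Gait-cycle detection assumes reasonably periodic walking; bouts with
  stops, turns, or missing markers are out of scope.
* MI magnitudes depend on the estimator's partitioning rules; comparisons
  across bands/channels within one estimator are meaningful, absolute values
  should not be compared across estimators.

## A worked example

```{r, eval = FALSE}
library(lfpdecode)

cfg <- synth_config(duration = 120, seed = 1,
                    gait = gait_model(cadence = 0.75),
                    coupling = coupling_spec(m = matrix(0.7, 8, 6)))
session <- generate_session(cfg)
prep <- preprocess_session(session)

res <- crossvalidate(prep, decoder = "pls")
mean_r2(res)

mi <- mi_matrix(prep$features, session$kinematics, session$kin_fs)
sort(apply(mi, 2, mean), decreasing = TRUE)
```
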