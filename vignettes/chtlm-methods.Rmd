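---
title: "Cross-subject EEG-to-fNIRS transfer learning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-subject EEG-to-fNIRS transfer learning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chtlm)
```

## The problem

Classifying motor imagery (MI) versus rest from functional near-infrared
spectroscopy (fNIRS) in clinical populations is limited by two factors:
very few labeled trials per subject (a session yields on the order of ten
task and ten rest trials) and strong physiological differences between
subjects. `chtlm` implements a cross-subject heterogeneous transfer-learning
pipeline that addresses both: a convolutional encoder trained on abundant
EEG motor-imagery data (the source domain) donates intermediate feature
maps to a lighter fNIRS encoder (the target domain) through an adaptive
feature-matching network, and the downstream classifier is a sparse
Bayesian extreme learning machine (SBELM) designed for small samples.

The two modalities have incompatible native feature spaces (microvolt
oscillations at hundreds of Hz versus hemodynamic concentration changes
at 11 Hz). The pipeline makes them commensurable by mapping both to 2-D
time-frequency images — STFT spectrograms for EEG, Morlet scalograms for
fNIRS — so that the encoders share an input geometry and feature maps can
be compared layer by layer.

## Pipeline stages

1. **Beer–Lambert conversion.** Raw dual-wavelength intensities
   (730/850 nm) become oxy-/deoxyhemoglobin concentration changes via the
   modified Beer–Lambert law: per channel and wavelength,
   `dA(t) = log10(I0 / I(t))`, and `dC(t) = eps^{-1} dA(t) / (d_cm * dpf)`
   where `eps` is the 2x2 extinction matrix, `d` the 30 mm source-detector
   separation, and `dpf` the differential pathlength factor (default 6.0
   at both wavelengths; the extinction table is configurable because
   published tables differ by a few percent).
2. **Channel selection** restricts to motor-cortex channels (16 in the
   emulated montage; both chromophores are retained).
3. **Band-pass filtering** with a 4th-order Butterworth, 0.01–0.2 Hz,
   applied forward-backward so the hemodynamic latency is not distorted.
   At 11 Hz sampling these band edges are tiny fractions of Nyquist and
   the direct 8th-order transfer function is numerically ill-conditioned,
   so the filter runs as a cascade of zero-phase biquads (conjugate pole
   pairs, one zero at `z = 1` and one at `z = -1` each) after removing
   the channel mean — algebraically the same band-pass, numerically
   stable (DC leakage below 1e-3 of the input amplitude, linearity to
   1e-10).
4. **Segmentation** cuts 10 s task and 10 s rest analysis windows at the
   event onsets.
5. **Time-frequency images.** EEG trials become STFT magnitude images
   (0.5 s Hann window, 50% overlap, 4–40 Hz); fNIRS trials become Morlet
   scalograms over pseudo-frequencies log-spaced across 0.01–0.2 Hz. Each
   channel plane is min-max normalized to [0, 1] (a constant plane is
   defined as all zeros rather than 0/0) and bilinearly resized to a
   square image; the channel planes stack into one multi-plane image per
   trial (2 chromophores x 16 channels = 32 planes). The wavelet uses
   unit-peak normalization — every scale responds identically at its own
   pseudo-frequency — so the scalogram ridge of a narrowband signal sits
   at the signal frequency; amplitude weighting across scales would be
   discarded by the per-plane normalization anyway.

## Encoders and the 3,904-kernel feature vector

The source encoder is a ResNet-34, the target a ResNet-18 (basic blocks,
stage widths 64/128/256/512), with feature taps at the four residual-stage
outputs. Counting main-path convolution output channels — the stem plus
two 3x3 convolutions per basic block, excluding 1x1 shortcut projections —
ResNet-18 has exactly `64 + 4*64 + 4*128 + 4*256 + 4*512 = 3904` kernels,
and the per-kernel deep feature vector is the spatial mean of each
kernel's raw activation map (pre-normalization, so the features are
batch-independent in evaluation mode). `tiny34`/`tiny18` variants (widths
8/16/32/64, 3x3 stride-2 stem, no max-pool, two resp. one block per
stage, 488/248 kernels) run the identical code path at desk scale; they
are this package's addition for fast experiments and tests, not a claim
about the full-scale system.

Because no deep-learning framework is assumed, the package ships its own
small deterministic conv-net engine: im2col patch extraction (C++) feeding
BLAS matrix multiplies, batch normalization, residual blocks, hand-derived
backpropagation (verified against finite differences in the test suite),
and SGD with momentum and cosine learning-rate decay. Everything is
seeded; identical configuration and seed reproduce training bit for bit.

## Adaptive feature matching

For every candidate pair (source stage `k`, target stage `d`) with
`k >= d` (coarse-to-fine transfer), three components interact:

* a **weight network** `f_phi`: a small fully connected net that maps the
  spatially pooled source feature map (length = source stage channels) to
  one nonnegative weight per source kernel (softplus output), normalized
  to per-sample mean 1 — mean-1 rather than softmax normalization keeps
  the matching-loss scale independent of the channel count so a single
  `beta` works across stages;
* a **channel aligner**: a learnable 1x1 convolution mapping the target
  map to the source channel count (the source map is bilinearly resized
  to the target's spatial size);
* the **weighted matching loss**
  `mean_n sum_c w_c ||u_c - v_c||^2 / C`, where `u_c`, `v_c` are the
  L2-normalized flattened source and aligned target maps of kernel `c`.

Transfer training minimizes `CE + beta * sum_pairs matching_loss` jointly
over the target encoder, the aligners and the weight networks by plain
first-order SGD (no bilevel meta-optimization: at these problem sizes the
joint update is stable and an order of magnitude cheaper). The matching
coefficient is held constant over training; a cosine-annealed variant
(full `beta` early, zero by the final epoch) was evaluated during
development and produced no measurable improvement on synthetic studies,
so the simpler constant form is kept. The source
encoder runs in evaluation mode only; its parameters receive no updates
(the tests assert its parameter hash is unchanged). Because the loss is
linear in the weights under the mean-1 constraint, the weight networks
shift mass toward source kernels whose normalized maps the target can
match — kernels carrying structure relevant to the target task — which is
the adaptive selection mechanism: more useful kernels, larger weights.
Since the frozen source's maps never change, they are evaluated, resized
and normalized once per training run and only indexed per batch.

Heterogeneous inputs are reconciled at the image level: both domains'
images share one plane count (the smaller stack is zero-padded), so the
source encoder can evaluate target images during transfer. With `beta = 0`
the code path reduces exactly to plain target training (asserted in the
tests).

## Per-kernel features, Mann–Whitney filter

After transfer training, each trial is summarized by the per-kernel
averaged deep features. Each feature column is tested for a location
difference between MI and rest trials with a two-sided Mann–Whitney U
test: exact p by complete enumeration of rank assignments when
`n1 + n2 <= 12` with no ties, otherwise the normal approximation with tie
and continuity corrections. Features with `p < alpha` (default 0.05,
uncorrected — the selection is a screening step inside cross-validation,
not an inference) are kept; if none passes, the 32 smallest-p features
are kept so the pipeline stays total. The filter is computed inside each
training fold only and applied unchanged to the held-out subject;
computing it on pooled data would leak test labels into the selection.

## Sparse Bayesian extreme learning machine

The classifier is a single-hidden-layer network whose input-to-hidden
weights and biases are random (Uniform(-1, 1), fixed, seeded; default
width L = 200, sigmoid activation) — only the hidden-to-output weights
are estimated. With a Gaussian likelihood and a Laplace (L1) prior on the
output weights, the MAP estimate is the L1-penalized least-squares
problem

```
beta_hat = argmin_b 1/2 ||H b - y||^2 + lambda ||b||_1,   y in {-1, +1},
```

solved by cyclic coordinate descent with covariance updates (tolerance
1e-8, warm starts along the lambda path). `beta = 0` exactly when
`lambda >= max|H^T y|` (the KKT bound), and the test suite checks the
solutions against an independent FISTA solver. The penalty is chosen on
the training fold by generalized cross-validation,
`GCV(lambda) = (RSS/n) / (1 - df/n)^2` with `df` the active-set size;
candidates using more than 60% of the degrees of freedom are excluded
because the GCV ratio degenerates as the fit approaches interpolation.
A full evidence-maximization treatment of the posterior is left as an
extension hook; the MAP formulation reproduces the properties that matter
here (sparsity, overfitting control, fast training). The plain-ELM
ablation (`classifier = "elm"`) replaces the L1 path with a 1e-8 ridge
solve — dense weights, otherwise identical.

Decision rule: score = `H beta`; label 1 (motor imagery) when the score
is strictly positive, so an all-zero model predicts rest — a
deterministic tie-break.

## Evaluation

Leave-one-subject-out cross-validation: for each held-out subject, the
target encoder is transfer-trained, features extracted, the filter and
SBELM fitted on the remaining subjects only, and all five metrics
(accuracy, AUC, recall, precision, F1; MI positive) are computed on the
held-out subject. AUC is the Mann–Whitney rank statistic of the scores
(ties get half credit), which the tests verify against trapezoidal ROC
integration; a single-class test fold yields an undefined AUC, reported
as missing and excluded from the mean with a warning. Per-fold seeds are
`seed + fold`, so a run is reproducible end to end.

## The synthetic study generator

No clinical recordings ship with the package; the generator emulates the
study design instead. fNIRS subjects produce 10 MI + 10 rest trials
(16 channels at 11 Hz, 15 s windows): MI trials add a canonical
double-gamma HRF (peak near 5–6 s, undershoot near 16 s, ratio 1/6 — the
standard parameterization; any smooth delayed response would do for
testing) convolved with the task boxcar on the "contralateral" half of
the channels, with HbR at -0.3 times HbO2 (a typical empirical
anticorrelation; the exact ratio is irrelevant to the tests). All trials
carry 1/f noise plus a Mayer-wave sinusoid drawn uniformly from
0.095–0.105 Hz at half the noise amplitude — deliberately inside the
pass-band edge. Subject variability is a log-normal response gain
(log-sd 0.2) and a normal latency shift (sd 0.5 s) of the response onset.
EEG subjects produce 4 s trials in which each class modulates mu-band
(8–13 Hz) oscillation amplitude over a class-specific channel block — an
amplitude surrogate for event-related (de)synchronization.

Two aspects of the noise model matter for realism. First, the Mayer wave
and half of the 1/f noise variance are *systemic*: one realization shared
by every channel of a trial, as in real recordings where superficial
physiology dominates. This is essential — with purely channel-independent
noise, any channel-aggregating feature averages the noise away at
`sqrt(n_channels)` and classification saturates at accuracy 1.0 even at
single-channel SNR 1/8, which no clinical cross-subject study attains.
Second, subjects differ substantially: a log-normal response gain
(log-sd 0.8, so weak responders exist, as in stroke cohorts) and a
latency shift (sd 1.0 s). The default magnitudes (`noise_sd = 4` against
a unit response, with those variability settings) were calibrated once so
that the desk-scale pipeline lands in the accuracy regime reported for
clinical cross-subject MI-fNIRS classification (mean leave-one-subject-out
accuracy in the high 0.8s to mid 0.9s, chance at zero effect) and were
frozen thereafter. What the generator does *not* model:
photon-migration forward optics, motion artifacts, subject-specific
activation topographies, EEG–fNIRS co-registration. Passing tests
therefore demonstrate that the pipeline recovers known structure under
controlled conditions — they are necessary, not sufficient, evidence
about clinical recordings.

The generator is also invertible down to raw optical intensities
(`hemo_to_raw_intensity`), which gives the Beer–Lambert stage an exact
round-trip test to 1e-8.

## Problem sizes and numerical choices

Desk-scale defaults — tiny encoders, 24x24 images, 16 wavelet scales,
batch size 28, 12 transfer epochs, 20 source epochs — were chosen so that
a full 8-subject leave-one-subject-out run completes in about a minute
per configuration on a single CPU while leaving the learning dynamics
intact; the full-scale setting (ResNet-34/18 on 224x224 images) is the
same code path. Other numerical choices, each of which is exercised by a
dedicated test: zero-phase biquad cascade for the band-pass; unit-peak
Morlet normalization; all-zero normalization of constant image planes;
exact-enumeration threshold `n1 + n2 <= 12` for the U test; coordinate
descent tolerance 1e-8; GCV degrees-of-freedom cap 0.6; score ties at 0
classified as rest.

## Known limitations

* The matching-loss form (L2-normalized map distance with learned
  per-kernel weights, mean-1 normalization, joint first-order training)
  is one member of a family of weighted feature-matching objectives; the
  package fixes this member and documents it rather than sweeping over
  the family.
* The SBELM is MAP-only; no posterior uncertainty is propagated.
* The Mann–Whitney filter is uncorrected for multiplicity by design
  (screening, not inference); with thousands of kernels the selected set
  contains false positives at rate alpha, which the downstream sparse
  classifier tolerates.
* Binary classification only (MI vs rest); the four-class EEG source is
  used for source pre-training, not multiclass target decoding.
* Analyses are offline; no real-time path is provided.
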