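# chtlm — cross-subject EEG-to-fNIRS transfer learning for motor-imagery classification

`chtlm` classifies motor imagery (MI) versus rest from functional
near-infrared spectroscopy (fNIRS) recordings in the regime that makes
clinical brain–computer interfaces hard: a handful of labeled trials per
subject and strong physiological differences between subjects. It
implements a heterogeneous transfer-learning pipeline that pre-trains a
deep convolutional encoder on EEG motor-imagery data (the source domain,
where trials are plentiful) and transfers its intermediate feature maps
into a lighter fNIRS encoder (the target domain) through an adaptive
feature-matching network, then classifies per-kernel deep features with a
sparse Bayesian extreme learning machine (SBELM).

The package is aimed at BCI/neuroimaging methods researchers who want a
complete, reproducible, dependency-light implementation of this pipeline —
including a synthetic EEG/fNIRS study generator, so every stage is testable
without access to clinical recordings.

## The method in brief

* **Preprocessing.** Raw dual-wavelength optical intensities (730/850 nm,
  16 channels, 11 Hz) are converted to ΔHbO₂/ΔHbR by the modified
  Beer–Lambert law, ΔC(t) = ε⁻¹ ΔA(t)/(d·DPF) with ΔA = log₁₀(I₀/I);
  band-passed at 0.01–0.2 Hz (zero-phase 4th-order Butterworth); cut into
  10 s task / 10 s rest windows; and rendered as per-trial time-frequency
  images — Morlet scalograms for fNIRS, STFT spectrograms for EEG — with
  one image plane per channel and chromophore.
* **Encoders.** Source ResNet-34, target ResNet-18 (plus `tiny34`/`tiny18`
  scaled-down variants for desk-scale work), with feature taps at the four
  residual stages. ResNet-18 contains exactly **3,904** main-path
  convolution kernels; the per-kernel spatial means are the deep feature
  vector.
* **Adaptive transfer.** For each candidate (source stage k, target stage
  d) pair, a small weight network f_φ maps the pooled source feature map to
  nonnegative per-kernel transfer weights w (mean 1), and training
  minimizes CE + β · Σ w_c‖u_c − v_c‖²/C over the target encoder, the 1×1
  channel aligners and the weight networks, where u, v are L2-normalized
  source/aligned-target maps. The source stays frozen.
* **Feature filtering.** Each of the 3,904 features is screened by a
  two-sided Mann–Whitney U test (exact by enumeration for small samples);
  features with p < 0.05 survive.
* **SBELM.** A random fixed hidden layer (L = 200, sigmoid) plus sparse
  output weights: the Laplace-prior MAP estimate
  argmin ½‖Hβ − y‖² + λ‖β‖₁, solved by coordinate descent with λ chosen by
  generalized cross-validation. A plain-ELM ablation (ridge, dense) is one
  flag away.
* **Evaluation.** Leave-one-subject-out cross-validation reporting
  accuracy, AUC (rank statistic, ties ½), recall, precision and F1, with
  MI as the positive class.

## Worked example

A complete desk-scale experiment on synthetic data — generate an
8-subject fNIRS study, train a synthetic-EEG source encoder, and run
leave-one-subject-out evaluation of the transfer pipeline:

```r
library(chtlm)

study <- generate_fnirs_study(synth_config(n_subjects = 8, seed = 1))
cfg   <- pipeline_config(beta = 0.5, seed = 1)
res   <- loo_cv(study, cfg)
res
#> Leave-one-subject-out results
#>  subject accuracy  auc recall precision    f1
#>       S1      1.0 1.00    1.0     1.000 1.000
#>       S2      0.7 0.80    0.4     1.000 0.571
#>       S3      1.0 1.00    1.0     1.000 1.000
#>       S4      1.0 1.00    1.0     1.000 1.000
#>       S5      0.9 1.00    1.0     0.833 0.909
#>       S6      0.9 1.00    0.8     1.000 0.889
#>       S7      1.0 1.00    1.0     1.000 1.000
#>       S8      0.9 0.98    0.8     1.000 0.889
#> mean: acc=0.925 auc=0.973 recall=0.875 precision=0.979 f1=0.907
```

Each row is one held-out subject (20 trials: 10 MI, 10 rest) scored by a
pipeline fitted on the other seven subjects. The mean row is the
unweighted average — here 92.5% accuracy and 0.97 AUC on synthetic
subjects whose noise level and inter-subject variability are calibrated
to the difficulty regime reported for clinical cross-subject MI-fNIRS
classification. Recall below precision means misses outnumber false
alarms: weak responders (like S2, a low simulated response gain) account
for most errors.

Individual stages are plain functions, e.g.:

```r
ts  <- generate_fnirs_subject(synth_config(seed = 1), "S1")
raw <- hemo_to_raw_intensity(ts)          # down to optical intensities
hem <- beer_lambert(raw)                  # and back via Beer-Lambert
img <- cwt_image(ts$data[1, , ], fs = 11) # one trial's scalogram stack
count_feature_kernels("resnet18")
#> [1] 3904
```

There is also a command-line entry point (`inst/scripts/chtlm`) driving
the same stages from a JSON/YAML config:

```sh
Rscript inst/scripts/chtlm all --config demo.json --out runs/demo --seed 1
```

Every run directory contains the resolved configuration, a log and an MD5
manifest of artifacts; identical config + seed reproduces the metrics
byte for byte.

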