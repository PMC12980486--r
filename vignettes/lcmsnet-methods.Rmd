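---
title: "Classifying raw LC-HRMS runs with depthwise 1D-convolutional ensembles"
author: "lcmsnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying raw LC-HRMS runs with depthwise 1D-convolutional ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcmsnet)
```

## The problem

Untargeted metabolomics with liquid chromatography coupled to
high-resolution mass spectrometry (LC-HRMS) conventionally requires peak
picking, alignment, gap filling and normalization before any statistical
model sees the data. Those steps are slow, parameter-sensitive and poorly
reproducible across toolchains. `lcmsnet` takes the end-to-end route: a
centroided run — a point cloud of (retention time, m/z, intensity)
triples — is binned into a fixed-shape *pseudoimage* and classified
directly by an ensemble of small convolutional networks whose structure
matches the geometry of LC-HRMS data. Compounds elute as one-dimensional
peaks along the retention-time (RT) axis and are sharply localized in
m/z, so the network convolves *only* along RT, with an independent kernel
per m/z channel (a depthwise convolution), and never mixes channels
before the final classification layer.

## From raw points to pseudoimages

**Binning.** A `bin_grid` partitions the RT x m/z plane into half-open
rectangles (the final bin of each axis is closed). Every point falls into
at most one cell; a cell's value is the **maximum** intensity among its
points, so a chromatographic apex survives binning regardless of how many
scan points share the cell. Points outside the grid are dropped and
counted (`n_dropped`) rather than silently clamped.

**Adaptive resolution.** RT bins are set to the instrument's scan
interval, so one bin corresponds to one acquisition cycle.
On the m/z axis a `density_prior` assigns fine bin widths to regions
expected to hold many metabolites and broad widths elsewhere.
`estimate_density_prior()` builds such a prior from data: it splits the
pooled m/z values at empirical quantiles and compares each region's point
density to the width-weighted median density along the axis. The shipped
full-scale default (`default_density_prior()`) uses 0.5 Th bins below
500 Th and 1 Th bins above, on a 720-bin RT axis — a 720 x 1400 input.
Uniform binning (`build_uniform_grid()`) remains available when no prior
knowledge exists.

**Scaling.** Each pseudoimage is min–max scaled per m/z column over the
RT dimension (`scale_minmax()`): every channel then spans [0, 1], which
is what per-channel convolutions assume, and systematic multiplicative
intensity differences between instruments cancel exactly. Columns with
constant intensity map to zero. Whether the scaling should instead be
global per image is genuinely open; both are provided
(`mode = "global"`), per-column is the default.

## The classifier

Each ensemble member is, in order: batch normalization of the input
channels, a depthwise 1D convolution along RT (`kernel_len` taps, one
kernel per m/z channel, no cross-channel mixing), non-overlapping max
pooling of window `pool_len` along RT (mimicking the extraction of the
strongest signal per channel per gradient segment), spatial dropout that
removes entire m/z channels during training, then flatten and a dense
softmax layer with an L1 penalty on its weights. Training minimizes
cross-entropy plus the L1 term with Adam, early-stops on the loss of a
stratified validation split (`val_fraction`), and restores the best
weights. The K members differ in their seed-derived initialization, their
validation split and their dropout draws; the ensemble predicts the
arithmetic mean of the members' class probabilities.

The layers are authored in this package (vectorized R around two small
compiled kernels for the convolution and pooling); training is therefore
bit-reproducible under a fixed seed, which the test suite exploits.

Parameters that matter, with the full-scale defaults
(`default_member_config()`):

| parameter | default | meaning |
|---|---|---|
| `kernel_len` | 9 | RT taps per depthwise filter (~9 s of gradient at 1 s scans); smooths over small RT shifts |
| `pool_len` | 64 | RT bins per max-pool window; larger values trade temporal detail for shift tolerance |
| `spatial_dropout_rate` | 0.2 | probability of silencing a whole m/z channel during training |
| `l1_coeff` | 1e-5 | sparsity pressure on the dense layer |
| `learning_rate`, `batch_size` | 1e-3, 32 | Adam settings |
| `max_epochs`, `early_stop_patience` | 50, 5 | training length control |
| `val_fraction` | 0.1 | stratified early-stopping split |
| K (`n_members`) | 5 | ensemble size |

With these defaults the full-scale five-member ensemble holds 469,025
trainable parameters (93,805 per member) — deliberately under half a
million, an order of magnitude below pretrained 2D-CNN alternatives. The
dense layer dominates the count, so `pool_len` is the main lever.

## Augmentation and class balance

Retention times drift between runs as columns age and instruments
change. `augment_dataset()` adds, per training sample, shifted copies
with a uniform RT shift of up to `max_shift` = 10 s applied to the raw
point cloud *before* binning; points pushed outside the acquisition span
are dropped. Applying the shift to the points rather than translating
the binned image keeps sub-bin shifts honest and exercises the binning
path; an integer bin translation is trivially available by shifting in
multiples of the bin width. Classes are balanced by random oversampling
(duplicates drawn with replacement) once per ensemble build.

## Decisions with a reject option

For high-stakes screening the classifier should abstain when unsure. The
confidence margin is the gap between the top two ensemble probabilities;
`classify_with_reject()` rejects a sample when its margin falls below a
threshold (threshold 0 never rejects). `select_threshold()` picks the
threshold on held-out training data (10% by default) by maximizing macro
one-vs-rest specificity over the *accepted* samples; candidates that
reject everything are disqualified and ties break toward the smallest
threshold, i.e. the fewest rejections. Rejected samples are excluded
from confusion counts — they receive no label, so they carry no
confusion information; whether they should instead penalize the
denominator is a design choice, and exclusion is ours.

## Evaluation protocol

`binary_metrics()` implements accuracy, sensitivity, specificity and F1
from one-vs-rest confusion counts; zero denominators yield `NA`, never a
silent zero, and `macro_metrics()` excludes such values from macro means
with an explicit count. Overall multiclass accuracy is reported
separately: under one-vs-rest the large "rest" group inflates per-class
accuracies above it, which is expected and tested. Splitting is
stratified (75/25 by default; `stratified_kfold()` for 10-fold model
comparison). `wilcoxon_signed_rank()` ranks paired per-fold differences
(mid-ranks for ties, zeros dropped), reports the rank sums and
`T = min(R+, R-)`, and computes the one-sided p exactly by full sign
enumeration for up to 15 non-zero differences, switching to a normal
approximation with tie and continuity corrections beyond that; the
one-sided default matches the hypothesis that one classifier outperforms
the other, and `bh_adjust()` applies Benjamini–Hochberg step-up control
across metrics.

## The synthetic generator

The generator (`sim_config()`, `simulate_dataset()`) emulates what the
method needs from centroided Q-TOF data, and nothing more: a 12-minute
(720 s) gradient sampled on a regular scan grid, class-specific marker
compounds (default 10 per class, disjoint across classes, plus 10 shared
compounds) eluting as Gaussian RT profiles (sigma 2–5 s) that emit one
centroid per scan at a fixed m/z, lognormal peak-height variation
(CV 0.3), a per-sample RT drift (Normal, sd 2 s) applied to all peaks of
a run, sparse exponential background centroids, and per-batch systematic
RT/m/z offsets and intensity response factors (`batch_profile()`). A
detection threshold at 1% of a compound's mean apex height truncates
elution tails, keeping point counts desk-scale; the cut is applied
before the batch intensity factor so the retained point set is
scale-invariant. Everything is a pure function of the seed.

What it does **not** model: isotope patterns, adducts, ion suppression,
m/z-dependent mass error, peak tailing, co-elution structure, or real
metabolite libraries. Passing tests on these simulations show that the
pipeline recovers class structure planted in raw centroided data under
drift, noise and batch effects — they do not certify performance on any
real cohort.

## Numerical and design choices

* Bins are half-open with a closed final bin; boundary points are
  assigned deterministically and out-of-span points are counted.
* Argmax ties break toward the lowest class index in the sorted
  `class_order`; pooling windows are non-overlapping and a partial
  trailing window is dropped.
* Batch normalization uses batch statistics during training and running
  averages (momentum 0.9) at inference; the L1 penalty applies to the
  dense layer only.
* One global seed fans out to every stage (simulation, splits,
  augmentation, member initialization, dropout) through a fixed integer
  mixing function, so a `run_config` reproduces a run exactly.
* The verification experiments are sized for a single CPU: the 5-class
  recovery benchmark uses 100 samples per class on a 240 x 150 grid with
  a K = 5 ensemble, and the cross-batch experiment 3 classes x 40
  samples per batch on a 360 x 150 grid with K = 2. The cross-batch
  simulation uses 2 s scans so the grid can actually resolve the 5 s
  batch offset it studies; with coarser bins the offset would vanish
  into a single bin and the comparison would be vacuous.

## Limitations

The m/z axis is treated as unordered channels: a mass-calibration shift
between batches moves signal across channels and is not absorbed by RT
augmentation (the generator can simulate it via `mz_offset`). Very small
classes limit the stratified validation splits each member uses for
early stopping. The network offers no feature-level explanation of its
predictions; inspecting `member_features()` gives channel-level
activations only.
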