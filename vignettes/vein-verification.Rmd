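---
title: "Finger-vein verification with pyramidal convolutions and scale-aware attention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finger-vein verification with pyramidal convolutions and scale-aware attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(veinnet)
```

## The problem

Finger-vein verification decides whether two near-infrared (NIR) images of a
finger's subcutaneous vein pattern come from the same finger. Deoxygenated
hemoglobin absorbs NIR light, so veins appear as dark, roughly longitudinal
ridges on a brighter tissue background in the region-of-interest (ROI) crop.
Vein images are low-contrast and mutually very similar across fingers, which
makes the *scale* of the features decisive: fine capillary texture, medium
vessel branches and coarse vessel topology all carry discriminative
information. veinnet implements a verification network built around that
observation, plus the open-set evaluation protocol used to score it.

The package is written so that every component is exercisable without access
to real finger-vein collections (which are distributed under restrictive
licenses): a seeded generator produces synthetic ROI images with
class-specific vein topology and realistic intra-class variation.

## The model

### Pyramidal convolution

A pyramidal convolution replaces one standard convolution with `n` parallel
grouped convolutions of increasing kernel size `K_1 < K_2 < ... < K_n`
(default 3, 5, 7, 9) and decreasing kernel depth, whose outputs are
concatenated. Under the idealized depth schedule in which level `i` uses
depth `FM_i * K_1^2 / K_i^2`, every level costs exactly
`K_1^2 * FM_i * FM_oi` weights -- each level is as cheap as a standard
`K_1 x K_1` convolution, so the enlarged receptive field is free in
parameters and FLOPs. `pyconv_param_count()` and `pyconv_flop_count()`
implement this accounting literally. Because the implied group count
`K_i^2 / K_1^2` is not an integer for kernels (3, 5, 7, 9), realized layers
use the practical group schedule (1, 4, 8, 16); `pyconv_realized_params()`
reports the realized count, and the two accountings agree exactly whenever
`K_i^2 / K_1^2` is an integer and the groups equal that ratio (e.g. kernels
3 and 9 with groups 1 and 9). Both numbers are reported by
`inspect_model()` so the equality claim stays testable independently of the
divisibility constraint.

### Scale-aware attention

The four per-scale feature maps are complementary but redundant; summing or
concatenating them indiscriminately drowns fine detail. The scale descriptor
module (SDM) computes, per image, a `C x C` matrix
`phi = softmax(Omega %*% Theta)` from two independent 1x1 reductions of the
`4C`-channel multi-scale map (`Omega` reshaped `C x N`, `Theta` `N x C`,
`N = H*W`). Read in 4x4 blocks of size `C/4`, `phi[i, j]` measures how much
scale `i` should draw from scale `j`. The scale attention module (SAM)
re-aggregates the compressed features `F` as
`refined_i = gate * sum_j phi[i, j] %*% F_j + F_i`.

Design choices the source material leaves open, and how this package
resolves them:

* **Softmax axis.** The row-wise softmax makes each descriptor row a
  distribution over the channels it attends to, the standard attention
  convention; the product `Omega %*% Theta` is the `C x C` reading
  consistent with the 4x4 block structure of `phi`.
* **Shared vs. independent reductions.** `Omega` and `Theta` use independent
  1x1 weights; the shared case is a special point of that family.
* **Gated skip connection.** The SAM aggregation is scaled by a learnable
  scalar gate initialized at 0 before the skip addition. At initialization
  the attended block therefore computes exactly the same function as the
  no-attention ablation, which makes the ablation a strict special case and
  protects early training from untrained attention noise.
* **Block-row aggregation.** Each refined scale uses its block row of
  `phi` over all scales, the only reading that actually mixes multi-scale
  information.

### Residual block and backbone

Each residual block computes: pyramidal convolution (4 scales, `4C`
channels) -> batch norm/ReLU -> 1x1 compression to the single-scale width
`C` -> scale-aware attention -> 1x1 expansion to the block width -> identity
shortcut (1x1-projected on downsampling) -> ReLU. The backbone is a stem
convolution (7x7, stride 2, then 3x3/2 max pooling) followed by four stages
of such blocks with stride-2 transitions.

The source design reports no backbone depth, stage widths, embedding size
or classifier-head layout. The package defaults are a compact profile --
widths 32/64/128/256, one block per stage, 256-dimensional embedding --
chosen so that a full train-plus-evaluate experiment on the synthetic
profile completes in minutes on a single CPU core (`network_config()`
scales the widths and depth up for GPU-class budgets), and a batch-norm
neck between the GeM descriptor and the linear classifier: the normalized
embedding feeds both the softmax head and the verification score, standard
practice in verification and re-identification models, adopted here to
stabilize head convergence and cosine geometry at short training budgets.
All experiments shipped with the package use the compact profile.

Attention-ablation comparisons are exactly paired: the SA parameters are
drawn on a fork of the RNG stream that is restored afterwards, so for a
fixed seed the attended and no-attention builds share identical shared
weights and identical downstream randomness (batch composition,
augmentation draws), and with the gate initialized at 0 they start as the
same function. Differences between the two training runs are then
attributable to the attention path alone.

### GeM global descriptor

The final feature map is pooled per channel with the generalized mean
`f_c = (mean(x^p_c))^(1/p_c)`, with a learnable exponent per channel
initialized at 3 (common practice in image retrieval). `p_c = 1` is exactly
average pooling (SPoC) and `p_c -> Inf` approaches max pooling (MAC), so the
network can interpolate between diffuse and peaked channel summaries;
exponents receive gradient like any other parameter. Activations are clamped
at a floor of `1e-6` before exponentiation, which keeps the power and its
logarithmic derivative finite on dead channels. Verification scores are
cosine similarities of L2-normalized GeM descriptors by default (the score
function is not dictated by the model; negated Euclidean distance is
available via `score_pairs(metric = "euclidean")`).

### Joint loss

Training minimizes `L = L_s + lambda * L_c`: mean softmax cross-entropy over
the training classes plus the center loss
`L_c = 1/2 * sum_i ||x_i - c_{y_i}||^2`, which pulls each embedding toward
its class center and directly shrinks intra-class distance that the softmax
term ignores. Two conventions are worth stating explicitly:

* The squared-norm form is used (the 1/2 prefactor pairs with the squared
  norm to give the clean gradient `x_i - c_{y_i}`).
* Centers are not optimized by the main optimizer: after every step each
  center appearing in the batch moves toward its batch class mean by the
  center learning rate (default 0.5), an exponential-moving update in the
  style of the original center-loss scheme.
* A class center is initialized at its first observed batch mean, not at
  the origin. The origin is not a center estimate, and pulling embeddings
  toward it in the first batches only shrinks their norms -- at short
  training budgets that transient can collapse the embedding and freeze
  softmax learning before clustering ever starts. First-sight
  initialization makes the center term a pure clustering force from step
  one. (The reference center-loss scheme does not prescribe an
  initialization.)

`lambda` balances the two terms; the grid explored on real data spans 0.01
to 5 with per-dataset optima around 0.1-2 (profiles exposed in
`loss_config()`).

## Training recipe

Defaults in `run_config()`: Adam at learning rate 0.001;
reduce-on-plateau scheduling (factor 0.1) on the per-epoch validation loss
with patience 20 -- patience is counted in epochs because that is the unit
at which a plateau scheduler observes validation loss, and a per-batch
patience of 20 would fire inside the first epoch; at most 100 epochs;
batches of 32 classes x 4 samples (128 images) drawn by the class-balanced
sampler; one held-out sample per class as the validation set (the
construction of the validation split is otherwise unspecified); geometric
augmentation re-drawn each epoch -- random vertical flip (probability 0.5),
no horizontal flip, rotation within ±2.5°, width/height shifts within ±5%,
shear within ±0.05, zoom in [0.95, 1.05] -- so the training set never grows.
Vertical-but-not-horizontal flipping is unusual for vein images but is
honored literally as specified. Exposed borders replicate edge pixels
(bilinear resampling with clamped coordinates). The parameters with the
best validation loss are kept as the returned model.

## Open-set evaluation protocol

Verification is scored on classes never seen in training: each fold splits
the classes half/half at random (seeded), the model embeds the test-class
images, and pairs are scored. Genuine pairs are all within-class pairs,
`N_g = N_c * N_f * (N_f - 1) / 2` on a balanced set (per-class
`choose(n_c, 2)` otherwise); impostor pairs follow the one-representative
convention `N_i = choose(N_c, 2)` -- one cross-class pair per unordered
class pair, using the first sample of each class under a seeded ordering --
with an exhaustive mode (`make_pairs(impostor = "exhaustive")`) for
robustness studies. "Fourfold" evaluation means four independent seeded
repetitions of the half/half split with metrics averaged; k-fold
partitioning is incompatible with half/half open-set splits.

At threshold `t` (accept when score >= t), FAR is the fraction of impostor
scores at or above `t` and FRR the fraction of genuine scores below `t` --
the standard biometric definitions; the printed formulas in the source
material assign both numerators to rejections over genuine attempts, which
cannot both be literal, so the standard forms are implemented. The EER is
the FAR/FRR crossing, linearly interpolated between the two bracketing
thresholds over the sorted union of scores, ties broken toward the lower
threshold. The accuracy threshold rule is unstated in the source; `Acc` is
reported at the accuracy-maximizing threshold, a documented convention.

## The synthetic generator

`generate_dataset()` emulates the structure of public finger-vein ROI
collections: many classes (fingers), six samples per class. Each class owns
a template of 3-8 smooth dark curves biased along the long finger axis
(cubic splines through random control points, Gaussian cross-sections,
occasional short branches) on a brighter tissue background with a smooth
illumination gradient. Each sample perturbs the template with affine jitter
on the augmentation scale (rotation ±2.5°, shifts ±5%), a multiplicative
low-frequency illumination field (±12%) and additive Gaussian sensor noise
(sigma 8 gray levels) -- values chosen once as representative of
consumer-grade NIR acquisition. The dataset is a pure function of the
configuration, including its master seed, byte for byte.

What the generator does *not* emulate: finger texture and skin reflections,
perspective/pose changes beyond affine, sensor fixed-pattern noise, and the
strong inter-session illumination drift of real devices. Tests passing on
synthetic data therefore demonstrate that the pipeline is implemented
correctly and can learn vein-topology class structure, not that the
printed accuracies on restricted real datasets are reproduced.

## Desk-scale experiment profiles

Unit tests use 20 classes x 6 samples at 64 x 64 (`synth_profile("test")`).
The end-to-end experiment profile (`synth_profile("smoke")`) uses 100
classes x 6 samples at 96 x 96, trained on one open-set half (50 classes)
with the compact backbone. These sizes were chosen so a full
train-plus-evaluate cycle is a minutes-scale computation on one CPU core
while leaving the class count large enough for a meaningful half/half
open-set split.

For the synthetic profile the center-loss weight was selected the same way
the per-dataset weights are selected on real data -- a small grid over
`lambda` judged on held-out verification error for one fold -- and then
frozen at 0. Every positive weight in the explored grid (0.003 to 0.5)
slowed or froze softmax learning and worsened the equal error rate at this
scale. The mechanism is worth recording: the center term's gradient
`lambda * (x_i - c_{y_i})` is directionally coherent across samples and
steps -- centers lag the embeddings they track, so the term acts as a drag
on any fast feature drift -- and under Adam's normalized updates a coherent
drag dominates the comparatively noisy cross-entropy signal whenever the
two are of similar magnitude. Over hundreds of epochs the drift slows and
the center term becomes the pure intra-class clusterer it is meant to be
(its clustering effect is verified directly on a toy problem in the test
suite); within a 30-step budget it never gets past the drag phase. The
real-data profile defaults (0.1/0.5/2) are unaffected.

## Numerical choices

* Convolutions run in single precision internally (im2col + BLAS GEMM; the
  per-output reduction depth is at most a few thousand, so float
  accumulation is ample); everything else is double precision. Forward
  passes are bit-reproducible across calls on a given platform.
* Batch-norm uses batch statistics in training and running statistics
  (momentum 0.1) in evaluation, so evaluation is deterministic.
* The GeM floor (1e-6), the softmax max-shift, and the log-sum-exp
  cross-entropy guard against overflow on degenerate inputs.
* All randomness (initialization, sampling, augmentation, splits, synthetic
  data) descends from explicit seeds; training runs are reproducible
  end-to-end from `run_config()$seed`.

## Known limitations

* The compact default backbone trades capacity for CPU tractability; the
  deeper residual profiles the design family implies are configurable but
  not exercised by the shipped experiments.
* The synthetic generator's realism gap (above) means absolute error rates
  on synthetic data say nothing quantitative about real sensors.
* Only the scale-aware attention and no-attention variants are implemented;
  squeeze-excitation, CBAM and related attention baselines are out of
  scope, as are identification (rank-N) metrics and ROI extraction from raw
  frames.
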