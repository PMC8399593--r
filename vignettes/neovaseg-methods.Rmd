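---
title: "Detecting retinal neovascularization by per-pixel semantic segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting retinal neovascularization by per-pixel semantic segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neovaseg)
```

## The problem

Proliferative diabetic retinopathy is marked by neovascularization: new,
fragile retinal vessels that grow as fine, tortuous tangles, often only one or
two pixels wide in a fundus photograph. Detecting them automatically is hard
because their growth pattern is irregular and their caliber is at the limit of
image resolution. Patch-level classifiers can say *whether* a region contains
neovascularization but not *where*; this package instead classifies every
pixel of a fundus image as `Neo` or `NotNeo`, which both detects and localizes
the lesions in one pass.

The package implements the complete experimental pipeline — synthetic data
generation, preprocessing, a compact encoder–decoder convolutional network,
training, and two-level evaluation — as deterministic, seeded functions, so
the whole experiment is reproducible from a single master seed.

## Synthetic fundus phantoms

Clinical fundus images with per-pixel neovascularization ground truth are
scarce and typically private. The phantom generator (`render_phantom()`)
provides a stand-in that preserves the *structural* properties the method
relies on:

* a dark background with a circular retinal field of view;
* a bright elliptical optic disk, offset from center;
* a recursively branching tree of normal vessels rooted at the disk, drawn
  darker than the background in all three channels with the largest contrast
  magnitude in green — the property that motivates green-channel extraction;
* zero or more neovascular lesions: dense tangles of thin (1–2 px), highly
  tortuous strokes radiating from a lesion center, confined to a disk whose
  radius is drawn from `lesion_radius_range`. Exactly the stroke pixels are
  marked `Neo` in the mask.

Default phantoms are 400 × 592 pixels: one-fifth linear scale of a
2000 × 2368 cropped clinical fundus image, rounded so that the network's
8-fold downsampling path and the 5 × 2 patch grid both still apply (patches
scale from 400 × 1184 to 80 × 296). Defaults — two lesions per phantom,
radius 18–30 px, twelve strokes per tangle, vessel trees of depth 5 with a
4 px trunk, additive Gaussian noise with standard deviation 5 — were chosen
once as plausible desk-scale analogues of clinical material: lesion tangles
occupy on the order of 1–3 % of the pixels, which reproduces the severe class
imbalance that dominates training on real data.

Lesion placement rejects overlap with the optic disk (disk
neovascularization is a separate clinical entity that this pipeline does not
localize) and between lesions, so connected components of the mask correspond
one-to-one to lesions.

What the phantoms do *not* model: exudates, hemorrhages, microaneurysms,
illumination gradients, or the photometric texture of a real retina. Passing
tests on phantoms therefore demonstrates that the pipeline's mechanics —
preprocessing, shape contracts, optimization, evaluation — are correct and
that the network can learn thin-tangle morphology; it does not certify
clinical performance.

## Preprocessing

The preprocessing order is fixed: green-channel extraction → CLAHE on the
full image → (optional crop) → patch tiling → per-patch min–max
normalization. Masks undergo only the geometric steps (crop, tiling, flips) —
never intensity transforms.

* **Green channel.** Retinal vessels have maximal contrast against the fundus
  background in green; red is near saturation and blue is noise-dominated.
* **CLAHE** (`apply_clahe()`) equalizes contrast locally over a tile grid
  (default 8 × 8) with a normalized clip limit (default 0.01: no histogram
  bin may hold more than 1 % of a tile's pixels; the excess is redistributed
  uniformly). The clip limit bounds noise amplification in flat regions.
  Per-tile lookup tables are blended bilinearly. With one tile and clip limit
  1 the operation reduces exactly to global histogram equalization, which is
  how the implementation is cross-checked. The clip limit and grid are
  exposed because no single value suits all sensors.
* **Patching** (`patch_grid()`, `split_patches()`) tiles an image
  deterministically in row-major order; `exact` mode requires the tiles to
  cover the raster exactly and `stitch_patches()` is then its exact inverse.
  The clinical-scale geometry — 2000 × 2368 images in 5 × 2 patches of
  400 × 1184, 200 patches from 20 images — is preserved at phantom scale as
  80 × 296 patches.
* **Normalization** (`normalize_patch()`) linearly rescales each patch to
  [0, 255] (a constant patch maps to 0), read as the simplest form of
  per-patch intensity normalization. Rounding is half-up, matching the
  reporting convention.
* **Augmentation** (`augment_flips()`) adds horizontal and vertical flips of
  every training patch — and only those two variants, because that is what
  triples a 100-patch training set to 300. Masks are flipped identically.
* **Splitting** (`split_dataset()`) partitions patches 50/25/25 into
  train/validation/test uniformly at random under a seed, with
  largest-remainder rounding so 200 patches give exactly 100/50/50.

Whether CLAHE should run on the whole image or per patch is genuinely
ambiguous in practice; this package runs it on the full image before
patching, matching the order above, so tile statistics are not truncated at
patch borders.

## The network

`build_reference_spec()` emits a declarative 42-layer plan (counting input
through softmax; the loss is not a layer):

| stage | layers | output channels | resolution |
|---|---|---|---|
| stem | 7×7 conv + BN + ReLU | 32 | full |
| pool | 2×2 max-pool, stride 2 | 32 | 1/2 |
| residual block 1 | 3×3 s2 / 1×1 s2 skip | 64 | 1/4 |
| residual block 2 | 3×3 s2 / 1×1 s2 skip | 128 | 1/8 |
| bottleneck | 1×1 conv + BN + ReLU | 128 | 1/8 |
| up 1, 2 | 4×4 s2 transposed conv + BN + ReLU | 64, 64 | 1/4, 1/2 |
| up 3 | 4×4 s2 transposed conv | 32 | full |
| skip | depth concat with stem ReLU | 64 | full |
| head | two 3×3 conv + BN + ReLU | 32, 32 | full |
| output | 1×1 conv + per-pixel softmax | 2 | full |

Design rationale, in brief: the 7 × 7 stem suits high-resolution inputs where
single-pixel vessels still benefit from wide context; 3 × 3 kernels follow
once resolution has dropped; 1 × 1 is used at the lowest resolution where few
pixels remain. The residual blocks downsample *and* add by putting a 1 × 1
stride-2 convolution on the skip path, so both paths agree in shape at the
element-wise addition. The single depth concatenation reuses the stem's
full-resolution feature maps in the decoder without increasing feature-map
resolution. Exact per-layer filter counts are not fully determined by these
constraints; the committed reconstruction above (32-64-128 encoder,
64-64-32 decoder, 32-32 head) honors every stated constraint, yields the
32 + 32 = 64 concatenation, and totals `r format(count_parameters(build_reference_spec(80, 296)), big.mark = ",")`
learnable parameters. Batch normalization is assumed present on the residual
skip paths.

Numerical choices: "same" padding everywhere (required by the
segmentation shape contract); transposed convolutions use 4 × 4 kernels at
stride 2 to avoid checkerboard artifacts; weights are He-initialized
(`sd = sqrt(2/fan_in)`) under a recorded seed, scaled by a gain of 0.3 for
every convolution except the output layer — those weights all sit upstream
of batch normalization, which makes them scale-invariant, so a smaller
initial norm raises their effective learning rate (the update direction is
unchanged, its relative step size grows as 1/‖W‖²), which matters under the
fixed small learning rate below;
an argmax tie (Neo probability exactly 0.5) is assigned `NotNeo`, the
conservative majority class. Probabilities sum to 1 within 1e-6 per pixel.

The forward/backward passes are implemented from first principles (blocked
im2col/col2im plus BLAS GEMM in compiled code; the GEMM inner path runs in
single precision, which is far below the gradient noise of stochastic
training) and backpropagation is verified against central finite differences
in the test suite.

## Training

`train_network()` runs stochastic gradient descent with momentum:
`velocity ← momentum·velocity − lr·gradient; parameters ← parameters +
velocity`, with mini-batch size 7, at most 10 epochs, momentum 0.9 and a
constant learning rate of 5 × 10⁻⁴ (only an initial rate is specified; no
schedule is applied). The loss is the mean over pixels of weighted
cross-entropy, `−w_c · log p(true class)`, with probabilities clamped at
1e-12. Class weights default to (1, 1) for fidelity to the original regime;
for phantom experiments a weighted mode compensates the ~50:1 class
imbalance (Neo pixels are rare), and the package uses (1, 25) in its own
end-to-end runs.

After every iteration (configurable via `validation_frequency`) the full
validation loss is evaluated. A patience counter counts evaluations whose
loss is **at or above** the running minimum and resets only when a new strict
minimum is reached — cumulative counting since the best, not consecutive
counting. Training stops when the counter reaches the validation patience
(default 4) or when the epoch budget is exhausted, and the parameters from
the best iteration are restored. The stopping rule is exposed as the pure
function `early_stopping_trace()` so it can be tested against hand-traced
sequences. Data order is reshuffled each epoch under the run seed, making
training bit-reproducible on a platform.

## Evaluation

`compute_metrics()` derives accuracy, sensitivity, specificity, precision,
Jaccard and Dice from pixel confusion counts with Neo as the positive class.
Undefined-value semantics are explicit and load-bearing:

* a metric with a zero denominator is **undefined** (`NA`), e.g. sensitivity
  on an image with no true Neo pixels;
* Jaccard and Dice are defined zeros when `TP = 0` but `FP + FN > 0`;
* averages are taken over the images where the metric is defined — undefined
  entries are excluded, never imputed as 0 or 1, while defined zeros count.

These conventions are exactly what reproduces the average row of the
published 50-patch clinical reference table shipped with the package
(`reference_segmentation_metrics()`): accuracy 0.9948 over 50 patches,
sensitivity 0.8772 over the 25 patches where it is defined, precision 0.8696
over 26, Jaccard 0.7643 and Dice 0.8466 over 26. Per-image means (not pooled
pixels) are used because they reproduce that row exactly. On the same table
the identities Dice = 2J/(1+J) and Dice = harmonic mean(precision,
sensitivity) hold to one unit in the fourth printed decimal (±1e-4) — the
operands are themselves rounded to four decimals, so agreement cannot be
tighter in general.

`patch_classify()` converts segmentation output to patch-level detection by
tiling masks into 200 × 296 tiles (8 per 400 × 1184 patch; 40 × 148 at
phantom scale) and calling a tile positive iff it contains at least one Neo
pixel, identically for prediction and truth. Patch-level metrics pool all
tiles into a single confusion matrix before deriving metrics, matching the
"400 image patches" reading of the reference evaluation.

## Problem sizes used in the shipped experiments

The package's own experiments are deliberately desk-scale: 400 × 592
phantoms in 80 × 296 patches for the learning-sanity experiment (four
lesion-bearing patches, at most 200 SGDM iterations at the fixed
hyperparameters, stopping once training-set Dice exceeds 0.9), and 160 × 160
phantoms in 80 × 80 patches for the end-to-end pipeline demonstration. These
sizes exercise every code path — 8-fold downsampling, the concatenation skip,
patch-grid round trips — while keeping a full run in minutes on one CPU.

## Known limitations

* Phantoms are structural, not photometric, models of fundus images; no
  claim about clinical accuracy follows from phantom results.
* The published per-layer filter counts are not fully specified; the
  reconstruction here is one committed, documented choice.
* Patch-level averages are pooled over tiles; per-image patch-level
  averaging would differ on heterogeneous test sets.
* Training at full clinical resolution (2000 × 2368) is out of scope for the
  shipped experiments, though the code is resolution-agnostic (dimensions
  divisible by 8).
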