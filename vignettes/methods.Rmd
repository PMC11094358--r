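---
title: "Counting wheat ears with density-map-augmented instance segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting wheat ears with density-map-augmented instance segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Estimating wheat yield starts with counting ears in field imagery. Field
scenes are hard: ears overlap, share color and texture with leaves, and
appear at densities from a handful to over a hundred per 1024x1024 tile.
Plain detectors miss occluded ears in dense patches; plain density
regressors count well but do not segment individual ears. `earcount`
implements a single model that does both: a YOLACT-style
prototype/coefficient instance segmenter whose backbone attention uses
generalized-mean (GeM) pooling and whose feature pyramid carries an
auxiliary Gaussian density-map regression branch, trained jointly and fused
at inference.

## The model

**Instance segmentation.** A convolutional backbone feeds a feature pyramid
(FPN). A shared head predicts, per prior box: an objectness score, class
scores (background/ear), box offsets (SSD-style encoding with variances
0.1/0.2), and k mask coefficients. A Protonet branch on the finest pyramid
level produces k prototype masks at input/4 resolution; a detection's mask
is `sigmoid(sum_j coef_j * prototype_j)`, cropped to its box and
thresholded at 0.5.

**GeM-CBAM attention.** After each backbone stage that feeds the pyramid, a
CBAM block gates channels then spatial positions. Every pooling operator
inside the block is a generalized mean
`GeM(x) = ((1/(HW)) sum x^p)^(1/p)`: `p = 1` is average pooling, large `p`
approaches max pooling. Each branch has one learnable exponent,
initialized to 11 (channel branch) and 19 (spatial branch); training floors
them at 1 and clips their gradients to [-1, 1]. Because each branch pools a
single GeM descriptor (replacing the original CBAM's max+average pair), the
channel MLP takes C inputs and the spatial convolution one channel. For
numerical stability GeM is computed as `M * (mean((x/M)^p))^(1/p)` with M
the (constant) group maximum — an exact identity, so gradients are exact.
Inputs are clamped at 1e-6 before exponentiation so fractional powers stay
real. The original max+average CBAM remains available (`attention =
"cbam"`) for ablations, as does no attention at all.

**Density branch.** Ground truth for each image is a density map: each
annotated ear contributes an isotropic Gaussian
`exp(-((a - a_i)^2 + (b - b_i)^2)/(2 sigma^2)) / (2 pi sigma^2)` centered on
its polygon centroid, evaluated at integer pixel coordinates and summed over
ears, so the map's total mass approximates the count. The full-resolution
map is generated once and rescaled to each pyramid level's shape by
mass-conserving pooling (exact block sums for integer factors; bilinear plus
global renormalization otherwise). A small head (two 3x3 convolutions with
softplus output, shared across levels) regresses these maps; its loss is
the mean over levels of the per-pixel MSE.

**Training objective.**

```
total = 1 * L_cla + 1.5 * (L_obj + L_box) + 6.125 * L_seg + w_density * L_density
```

with cross-entropy classification over positives and 3:1 hard-mined
negatives, binary cross-entropy objectness over the same counted set,
smooth-L1 box regression averaged over positives, and assembled-mask binary
cross-entropy cropped to each ground-truth box. The objectness bias is
initialized to the prior-probability value `-log((1-0.1)/0.1)` so the
overwhelming negative majority does not produce a destabilizing gradient
spike in the first iterations — without it, a fraction of small from-scratch
runs collapse to an all-background detector. `w_density` defaults to 1,
chosen so the density term starts within an order of magnitude of the other
terms on synthetic scenes. Priors match ground truth at IoU >= 0.5
(negative < 0.4, in between ignored), with every ground truth guaranteed
its best prior. Hard-negative mining is a deliberate deviation from summing
all priors, which would be dominated by the overwhelming negative majority;
it is standard detector practice and is required for the objectness term to
be trainable.

**Inference fusion.** Scores are objectness times class probability,
modulated by the predicted density sampled at the box center on the prior's
own level: `s' = s (1 + alpha min(d_local, 1)) / (1 + alpha)` with
`alpha = 1`; `alpha = 0` disables the fusion. The modulation is bounded and
scene-independent by design: an earlier variant that normalized by the
scene's maximum predicted density rescaled every score by a scene-dependent
factor, which breaks any absolute score threshold when the density scale
shifts between calibration and test scenes. Greedy NMS at IoU 0.5
(deterministic, in place of YOLACT's Fast NMS) selects survivors.

## Choices the sources left open

- **Instance center**: area-weighted polygon centroid, not bbox center —
  invariant to vertex density and starting vertex.
- **sigma**: not stated anywhere; default 8 px at 1024x1024, scaled
  proportionally with input size (1 px at 128). One fixed sigma per run, not
  geometry-adaptive.
- **Kernel truncation** at 4 sigma (mass error < 4e-4 per target); border
  Gaussians are *not* renormalized, matching the literal summation formula,
  so border targets contribute slightly less than unit mass. This bias is
  visible (and documented) rather than hidden.
- **Bias sign**: `Bias = mean(y - y_hat)` as printed in the defining
  formula; note that under this convention a *positive* bias means the
  prediction is *low* on average, the opposite of the usual prose reading.
  The printed formula wins.
- **AP interpolation**: COCO's 101-point envelope; the all-point variant is
  kept for hand-checkable oracles. mAP averages IoU 0.50:0.05:0.95, on
  masks (the evaluation is of segmentation quality).
- **Eq-level ambiguity on the semantic term**: the per-pixel segmentation
  loss is realized as the assembled-mask cross-entropy; no separate
  semantic-segmentation head is added (the architecture diagram shows
  Protonet plus heads only).
- **Density fusion site**: the detection-branch fusion is implemented (the
  sources mention both a Protonet-side and a detection-side combination;
  the described inference behaviour is detection-side).
- **Prior boxes**: one scale per level (2x stride for the tiny backbone, 4x
  for resnet101), aspect ratios {1, 0.5, 2}; the source papers never state
  theirs.

## Desk-scale protocol

The full-scale configuration (ResNet-101 bottleneck backbone, 1024x1024
inputs, k = 32 prototypes, SGD momentum 0.9, lr 0.001, batch 8) is
constructed faithfully but is not trainable on a laptop-class CPU, and the
reference datasets require large downloads. All quantitative checks
therefore run a `tiny` backbone (four plain conv stages of width 16/32/48/64,
pyramid at strides 8/16, k = 8) on synthetic scenes:

- **Smoke training**: 32 scenes at 128x128 (density levels 1–2), 200 SGD
  iterations, batch 8, momentum 0.9, learning rate 0.02. The higher
  learning rate is the tiny protocol's own choice: 0.001 presumes a
  COCO-pretrained full-scale backbone and barely moves a from-scratch tiny
  model in 200 iterations, while 0.04 destabilizes it.
- **Counting operating point**: a briefly trained model's scores are not
  calibrated — held-out ears are detected at IoU 0.6–0.85 but with scores
  spread from 0.08 upward, so any fixed absolute threshold is arbitrary.
  `calibrate_score_threshold()` picks the threshold minimizing counting
  RMSE *on the training scenes* (never held-out data) and stores it in the
  model config. The uncalibrated default remains 0.3.
- **Ablation repeats**: the density-vs-no-density comparison uses 10 seeded
  repeats of a reduced benchmark (64x64 scenes, 10 training scenes at
  levels 2–3, 60 iterations, batch 4, 8 held-out scenes) and asserts only
  the direction of the difference, not magnitudes.

## What the synthetic scenes do and do not show

`generate_scene()` draws golden textured ellipses ("ears": random
orientation, per-ear brightness, longitudinal banding, speckle, and an
awn-like stroke fringe) over a green-brown background with leaf-like
clutter strokes, some deliberately in ear-similar dry-leaf hues. Ground
truth is the exact 16-vertex ellipse outline. Four density levels span
5–15 up to 80–150 ears at 1024x1024 (4–8 up to 28–40 at the 128 test
scale, keeping the painted-area fraction comparable). Center placement uses
rejection sampling with a level-dependent minimum spacing, so higher levels
allow progressively heavier overlap.

Passing on these scenes demonstrates that the losses, gradients, matching,
mask assembly, density supervision and metrics are implemented correctly
and that the full pipeline can learn to count; it does **not** demonstrate
field-level accuracy. Real imagery has perspective, illumination variation,
soil, motion blur, and morphology the generator does not attempt
(photorealism is an explicit non-goal).

## Numerical notes and limitations

- Convolutions are im2col gathers plus BLAS matrix products; gradients use
  precomputed sort/cumsum scatter plans. Everything is double precision and
  single-threaded-deterministic: fixed seeds reproduce loss histories
  bitwise.
- Greedy NMS and greedy detection–gt matching break ties by order after an
  initial stable sort on scores.
- Degenerate inputs: empty center sets give zero maps; images with no
  annotations train with box/mask terms of zero; constant true counts make
  R^2 undefined (returned as NA with a warning); two empty masks have IoU
  defined as 0 with a warning.
- Training aborts with a diagnostic naming the first non-finite loss
  component.
- The resnet101 configuration is structurally faithful (bottleneck stages
  3/4/23/3) but omits batch normalization (per-image training on CPU), uses
  three pyramid levels, and loads no pretrained weights; it is retained as
  a configuration reference, not a benchmarked model.
- RLE mask encodings, multi-class taxonomies, Fast NMS, GPU execution and
  FPS benchmarking are out of scope.
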