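---
title: "Tracking the brainstem to localize posterior-circulation thrombi"
author: "polartrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking the brainstem to localize posterior-circulation thrombi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(polartrack)
```

## The problem

Occluding thrombi of the posterior cerebral circulation — vertebral (VA),
basilar (BA) and posterior cerebral (PCA) arteries — are small objects
(median around 0.15 mL) in large CT volumes. A segmentation network applied
everywhere in the scan finds most thrombi but drowns them in false
positives, because hyperdensities that look locally like a thrombus occur
all over the head. The posterior circulation, however, hugs the brainstem,
whose position is highly predictable. `polartrack` implements a method that
exploits this: a moving volume-of-interest (VOI) is *steered along the
brainstem*, and segmentation only ever happens inside the tracked VOI.

Two networks are involved:

* **BL-UNet** — a 3D residual U-Net over a `(W, W, D)` VOI (full scale
  192 x 192 x 8 voxels). Down path: two k3 convolutions, max-pool, then
  three residual blocks with pooling after the first two; up path: a
  transposed convolution (k3, stride 2) and twice (residual block +
  transposed convolution), with skip concatenations; head: k3 convolution,
  k1 convolution, per-voxel sigmoid. All backbone normalizations are group
  norm with 4 groups. As a baseline it is applied on a non-overlapping
  grid of VOIs covering the scan.
* **Polar-UNet** — the same backbone, frozen, plus steering heads.
  Features from the four levels of the down path each pass one k3
  convolution (base-channel width, batch norm, ReLU), are globally
  average-pooled, concatenated with the VOI's relative `(z, y, x)`
  position in the scan, and feed two shared 256-unit fully connected
  layers and three heads: an **angle** (tanh), a **radius** (sigmoid) and
  a 3-class **action** (softmax: move / segment-and-ascend / stop).

At inference the VOI starts at the centre of the most caudal slice. A
*move* action displaces the VOI in-plane by the predicted polar step (at
most 10 moves per slice; a move that would leave the volume ascends and
re-centres instead); *segment-and-ascend* writes the VOI's segmentation
into the output (overlaps combine by voxelwise maximum) and ascends one
slice; *stop* terminates. Termination is guaranteed within
`Z * (maxMoves + 1)` forward passes. Predicted components at or below
0.065 mL are removed afterwards (volume-based removal, VBR).

## Supervision geometry

The reference annotation is one path voxel per axial slice through the
brainstem. For a VOI centred at `c` on slice `z`, with same-slice path
point `p`:

* `d = ||p - c||` (in-plane, voxels), direction `theta = atan2(drow, dcol)`
  measured from the +col axis toward +row, in `[0, 2 pi)`.
* radius target `min(d, W) / W` — the radius is capped at the VOI width
  and normalized to `[0, 1]` (sigmoid head).
* angle target `theta / pi - 1` in `[-1, 1)`. The angle can equivalently be
  reported on a `[0, 2)` scale (`theta / pi`); we store the symmetric form
  so the tanh output range is fully used. `applyPolarMove()` inverts this
  encoding exactly: for `d <= W` the reference move lands on the path
  within one voxel of rounding, for `d > W` it contracts the distance by
  exactly `W`.
* action target: *segment-and-ascend* when `d <= tol` (default `tol = 8`
  voxels), *move* otherwise, *stop* above the annotated range. The
  distance rule is our choice; only the three action classes themselves
  are inherent to the method.

Training VOIs are sampled so that exactly 40% contain thrombus (negative
candidates touching the thrombus are rejected). Augmentation applies one
in-plane rotation (±10°), left-right flip (p = 0.5), magnification
(0.9–1.1) and translation to image, mask *and* path points with the same
affine map, so targets recomputed after augmentation remain consistent
(verified to 2° / 2 voxels in the tests).

## Training recipe

Both stages use Adam, the focal loss (`alpha = 0.25`, `gamma = 2` —
the canonical values of the cited loss, as the originating recipe leaves
them unstated) for voxel and action classification, L2 for angle and
radius, and a triangular cyclical learning rate: `2e-5` to `1e-3`, linear
ramps of 300 iterations (full scale). Weight decay is `2e-6` for backbone
pre-training and `2e-5` for polar training. The backbone is pre-trained
alone (300 epochs x 148 iterations, batch 32 at full scale), then frozen
while the polar heads train (100 epochs, batch 128); the heads' added
layers use batch normalization. Because the decoder is frozen during
polar training, the focal segmentation term carries no gradient there; it
is computed and logged for monitoring. The four loss terms are equally
weighted (unstated in the original recipe; we chose 1.0 each and expose
them). The segmentation output bias is initialized to the foreground base
rate (`logit(0.01)`), the standard prior initialization for the focal
loss, which removes the early background-suppression phase.

Evaluation uses stratified 5-fold cross-validation with the occlusion
location as stratification variable (the only categorical per-case
variable reported per stratum); fold 1 is reserved for hyper-parameter
selection and excluded from aggregates (`makeFolds()`).

## The phantom generator

No public dataset exists for this task, so the package ships a synthetic
head phantom (`generatePhantom()`) that exercises every code path:

* soft tissue at 35 HU (the NCCT window centre) with Gaussian noise
  (sd 5 HU), a skull shell at 700 HU, air outside the head;
* a smooth sinusoidal brainstem path (one point per slice, per-slice step
  bounded by 3 voxels) ascending through 80% of the slices;
* a CTA channel with a 300 HU contrast-filled artery (radius 2 mm) along
  the path — saturated exactly by the [-100, 200] HU clip, as clinically —
  interrupted over the thrombus extent (filling defect);
* an NCCT thrombus segment at 60 HU (hyperdense artery sign range), whose
  axial extent and in-plane radius are *solved* so the rasterized volume
  matches a target drawn from a log-normal with median 0.15 mL and log-sd
  1.15 (chosen so the quartiles sit at `0.15 * exp(±0.6745 * 1.15)`, i.e.
  near 0.07 and 0.33 mL, matching the reported cohort IQR; the printed IQR
  is nearly symmetric on the log scale, which makes the log-normal the
  minimal consistent model);
* hyperdense distractor blobs (60–200 HU, radius 0.8–1.8 mm — all below
  the 0.065 mL VBR threshold) placed at least 20 voxels in-plane from the
  path at every slice they span;
* location categories (VA / BA / PCA and their combinations) map to the
  caudal / middle / cranial thirds of the path; the default category mix
  follows the reported cohort strata, plus a 2/187 chance of a scan with
  no visible thrombus. A sampled volume that cannot fit its section
  (tail probability about 0.2% with the 6 mm maximal radius) raises an
  error; cohort generation retries such a case with a derived seed.

What the phantom does **not** emulate: real anatomy, beam hardening, CT
physics, registration error between CTA and NCCT (channels are aligned by
construction), and realistic intensity statistics of thrombus versus
brain (no such statistics are published for this cohort; the contrast is
a documented free parameter, not a fit). Passing tests on phantoms
therefore demonstrate the correctness of the machinery — geometry,
tracking, losses, metrics — not clinical performance.

## Desk-scale profile and problem sizes

The shipped desk profile (`deskNetConfig()`, `deskTrainConfig()`) runs
the same code paths at VOI 32 x 32 x 8, 8 base channels, 15 x 20
iterations (batch 4) for the backbone and 8 x 20 iterations (batch 8) for
the heads, a 50-iteration learning-rate ramp, and an augmentation shift
capped at 10 voxels to match the 96-voxel phantom field of view. Phantoms
default to 64 x 96 x 96 voxels at (2.0, 0.5, 0.5) mm. These sizes train
and evaluate an end-to-end pipeline on a single CPU in minutes; the
full-scale configuration is expressed by `netConfig()` / `trainConfig()`
defaults.

## Numerical and design choices

* **Engine.** The 3D layers (convolution as im2col + BLAS GEMM,
  transposed convolution as its exact adjoint, max-pooling, group/batch
  norm, Adam) are implemented in the package with C++ kernels; every
  backward pass is validated against central finite differences in the
  test suite. Evaluation-mode forwards are deterministic.
* **Skull-top detection** for the 25 cm crop: the most cranial slice with
  any voxel above 300 HU (typical cortical bone); configurable. The
  originating description does not define "top of the skull".
* **Binarization** at probability 0.5; overlapping tracker writes combine
  by voxelwise maximum (order-independent and conservative).
* **Out of bounds** means any part of the VOI would leave the in-plane
  volume extent.
* **Action ties** resolve to *move* (lowest index), making the bounded
  move budget the binding constraint.
* **Overlap denominators** in component matching follow the literal
  reading of the FP and FN definitions: the predicted component's size for
  FP status, the reference component's size for FN status (a
  min-denominator variant is available).
* **ICC form**: two-way random effects, absolute agreement, single
  measures — ICC(2,1) — with the F-based 95% CI; volumetric agreement is
  an absolute-agreement question.
* **Paired nonparametric test**: the described rank-sum test is
  internally inconsistent with paired metrics; we default to the Wilcoxon
  signed-rank test and keep rank-sum behind a flag.
* **Connectivity** 26 by default (thin elongated thrombi; configurable
  6/18/26). **VBR** removes components with volume `<= 0.065` mL
  (strictly larger survive).
* **Indexing**: public API is 1-based, arrays are `(z, y, x)` with slice 1
  most caudal. Angle/radius operate in voxel units (the radius unit is
  unstated in the original description; voxels keep the move operator
  integer-friendly).

## Limitations

The clinical headline numbers of the originating study are not
reproducible here: they require private registry scans and GPU-scale
training. The package's claims are therefore structural — exact metric
arithmetic against oracles, exact geometric inverses, conservative
theorems (VBR can only delete; recall after VBR never exceeds recall
before), and a scaled-down demonstration that the full pipeline trains
and recovers phantom thrombi end-to-end.
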