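---
title: "Automated skeletal age estimation from 3D CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated skeletal age estimation from 3D CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Estimating the chronological age of adult remains is a core task in forensic
medicine. For adults the informative signal is skeletal *degeneration* —
cortical bone loses mineral density and thins with age — and two practical
age indicators on whole-body post-mortem CT (PMCT) are the mandible and the
femur. Manual scoring of such indicators is laborious and reader-dependent;
`osteoage` implements a fully automated alternative: bone voxels are
extracted from the CT by deterministic preprocessing, and a 3D convolutional
network regresses age directly from them, optionally fusing both bones and
the subject's sex.

Because PMCT archives are not publicly distributable, the package ships a
synthetic CT *phantom* cohort generator with a known, parameterized age
signal. Every stage — DICOM I/O, preprocessing, networks, training,
cross-validated evaluation — is exercisable end-to-end on phantoms, and the
test suite uses them to verify that the pipeline actually recovers an age
signal it is known to contain.

## From DICOM to bone voxels

**DICOM ingestion.** A scan is a directory of axial slices. The reader sorts
slices by their position along the stacking axis, rejects mixed series,
duplicate positions, and slice spacings that deviate by more than 5%
(relative), and repairs a missing slice-thickness tag as the median
inter-slice position difference. Stored pixel values are converted to
Hounsfield units by the rescale affine `HU = slope * stored + intercept`;
when the rescale tags are absent the CT convention slope 1 / intercept
-1024 is assumed, with a warning. Axis order is `(z, y, x)` everywhere, so
"112 x 128 x 128" means 112 axial slices.

**Isotropic resampling.** Scanner spacing varies between scans (e.g. 1.2 mm
slices with 1.1 mm pixels vs 0.8/1.12 mm); every volume is resampled to
1 x 1 x 1 mm by trilinear interpolation (masks, where needed, use nearest
neighbour). The output grid has `round(dim * spacing / target)` voxels per
axis, which preserves the physical extent to within one voxel.

**Femur.** Femoral cortical bone lies roughly between 400 and 1000 HU, so
the volume is windowed: `clamp((HU - 400)/600, 0, 1)` sends 400 HU to 0 and
1000 HU to 1. The region is then centre-cropped / symmetrically zero-padded
to the fixed shape 112 x 128 x 128.

**Mandible.** Extraction is harder because neck-bone fragments share the
intensity range. Per axial slice: centre-crop to 256 x 256; threshold at
400 HU; morphological opening (erosion then dilation, 3 x 3 square
structuring element) to remove speckle; connected-component labeling
(8-connectivity); retain components whose area is at least 10% of the
largest (the mandibular arch survives, small neck fragments do not); mask
the HU slice. Bone-bearing slices are stacked and a central slab of exactly
20 slices is kept, then window-normalized with the same 400-1000 HU map.

Design points the source material leaves open, decided here once:

* **Anatomical localization.** Which sub-box of a whole-body stack holds
  each bone is accepted as an explicit region per subject, with an "auto"
  axial-band heuristic (mandible near the stack top, femur mid-shaft band)
  for phantoms. Configurable and logged.
* **Mandible slab.** A 20 x 256 x 256 voxel at 1 mm cannot hold a full
  mandible; the slab is taken as the central 20 bone-bearing slices
  (configurable), and the final [0, 1] normalization mirrors the femur
  window, which is stated explicitly only for the femur.
* **Component rule.** "Keep the largest areas" is implemented as *keep
  every component at least 10% of the largest*; the largest always
  survives.
* **Opening structure and connectivity** (3 x 3 square; 8-connectivity per
  slice) are conventional defaults; both are arguments.

## The regression models

A backbone `F` maps a bone voxel `X` to an embedding `feature_X = F(X)`; a
fully connected head maps the embedding — concatenated with a 32-wide
ReLU embedding of the binary sex code (0 male, 1 female) — to the scalar
age. Training minimizes the mean squared error between predicted and true
ages.

Backbones (all convolutions 3D, batch norm + ReLU, global average pooling):

* `resnet34_3d` — four stages of *basic* residual blocks (two 3x3x3
  convolutions skipped by an identity shortcut), block counts 3/4/6/3,
  stage widths 64/128/256/512 at full scale; feature width 512. Default
  for the mandible.
* `resnet50_3d` — four stages of *bottleneck* blocks (1x1x1 reduce, 3x3x3,
  1x1x1 expand; the shortcut skips three convolutions), widths x4 on
  output; feature width 2048. Default for the femur.
* `mobilenet_3d`, `squeezenet_3d` — depth-inflated depthwise-separable and
  fire-module variants, provided as lighter alternates.

One property worth noting: under full kernel inflation to 3D, the
basic-block ResNet-34 carries *more* parameters than the bottleneck
ResNet-50 (the 2D ordering reverses because 3x3x3 kernels triple the cost
of basic blocks); the test suite pins both counts against closed-form block
arithmetic rather than assuming the 2D ordering.

**Fusion.** Three strategies combine the two bones:

* *Late*: two independent gender-aware single-modality models; the final
  estimate is the exact arithmetic mean of their predictions (no learned
  parameters).
* *Middle*: mandible features, femur features, and the sex embedding are
  concatenated and fed to a joint head; gradients flow into both backbones.
* *Early*: both voxels are resampled to a shared 64 x 128 x 128 grid and
  stacked as two input channels of a single backbone. The source taxonomy
  describes early fusion in one sentence; this channel-stacking reading is
  the simplest one that keeps a single model, and it includes the sex
  branch for consistency with the other modes.

## Training

Defaults follow the reference recipe: Adam with minibatch 16, weight decay
1e-4 and first-moment coefficient 0.9 ("momentum 0.9" is read as Adam's
beta1, since Adam has no classical momentum; beta2 = 0.999), learning rate
3e-4 with floor 3e-5, up to 50 epochs. The learning rate is multiplied by
0.8 when the validation loss has plateaued for 10 epochs ("10 iterations"
is read as validation epochs, because validation loss exists only per
epoch); an improvement is a relative decrease of more than 1e-3 below the
running best. Augmentation randomly crops mandible voxels to 20 x 224 x 224
and femur voxels to 112 x 112 x 112; evaluation uses deterministic centre
crops. The best epoch is chosen by validation MAE (ties to the earlier
epoch). Because the cross-validation protocol defines no inner split, each
training fold is split 90/10 (stratified, seeded) to drive the scheduler and
checkpoint selection — the held-out test fold is never touched during
training, and this is asserted at run time.

*Progressive input-size transfer*: models are first trained at reduced
input sizes, and the weights initialize training at the next size. Global
average pooling makes every parameter shape input-size independent, so all
parameters (and batch-norm running statistics) transfer between rungs;
shape-incompatible parameters, if any, keep their fresh initialization, and
ladders mixing backbones are refused.

The output head bias is initialized to the mean training age, so epoch 0 is
exactly the predict-the-mean baseline and the network only has to learn the
deviation.

## Evaluation protocol

Stratified k-fold cross-validation (k = 10 by default): folds are disjoint,
differ in size by at most one, and preserve the age/sex distribution —
"same distribution" is made concrete as *age decade x sex strata balanced
to within one subject per fold*. The plan is a function of subject ids and
the seed, not of row order. Reported metrics per fold and as mean +/- std
(unweighted mean across folds; population std):

* MAE `(1/n) sum |y - yhat|` (years),
* Pearson correlation `cov(y, yhat) / (sd_y sd_yhat)`,
* Lin's concordance correlation coefficient
  `2 rho sd_y sd_yhat / (sd_y^2 + sd_yhat^2 + (mu_y - mu_yhat)^2)`.

Moments use population (1/n) normalization, matching the expectation-form
definitions of these quantities. Degenerate inputs are defined rather than
NaN: a constant side makes Pearson an error ("undefined correlation"); CCC
of two identical constants is 1, of two different constants 0.

## The phantom cohort

The generator emulates the one property the pipeline must detect — an age
signal carried by bone density and geometry — inside CT-like axial stacks:

* cortical density `h0 - beta*age + delta*sex + subject offset + voxel
  noise`, with defaults h0 = 800 HU, beta = 4 HU/year, delta = -30 HU for
  females, i.i.d. Gaussian voxel noise of 30 HU, and a per-subject,
  per-modality density offset of 20 HU so the two bones carry complementary
  noisy copies of the signal (giving fusion something to gain);
* cortical thickness `t0 - gamma*age` (8 mm at age 0, thinning 0.06
  mm/year), adding a geometric signal;
* femur region: a cortical-shelled cylinder (shaft) plus a spherical head —
  the head deliberately mimics the hip-bone contamination caveat of
  threshold-based femur segmentation;
* mandible region: a U-shaped cortical arch per slice plus a small separate
  "neck" cylinder, below 10% of the arch area by construction, which the
  component-retention rule must remove;
* cohort structure: ages from a truncated normal (mean 49.59, sd 11.80,
  range 20-70 years), 76% male — the demographic profile of the adult PMCT
  population this pipeline targets;
* parameter validity requires the oldest, lowest-density cortical bone to
  stay above 450 HU, safely inside the 400-1000 window.

Volumes are generated on 2 mm grids (femur 40 x 64 x 64, mandible
12 x 64 x 64) and pass through the *real* resampling path to 1 mm; the
generator writes genuine DICOM series so the reader is exercised too.

What the phantom does **not** emulate: real anatomy, beam hardening, metal
artifacts, scanner-specific noise spectra, nonlinear aging, or damaged
bones. Passing the end-to-end checks therefore shows that the
implementation is correct and can recover a linear density/geometry age
signal through the full chain — it does not certify accuracy on real PMCT.

## Desk-scale study sizes and numerical choices

The end-to-end studies in the test suite and the acceptance script run the
identical code path at reduced size, chosen once as the package's standard
desk configuration: cohort n = 200 (seeded), 3-fold cross-validation,
`scale = 1/8` (stage widths 8/16/32/64; femur input 14 x 16 x 16, mandible
2 x 32 x 32), 20 epochs. A desk-scale run takes roughly an order of
magnitude fewer optimizer steps than a full-size run (hundreds rather than
thousands), so its learning rate is raised by the same order, to 3e-3; the
package defaults keep the full-size recipe. Under these conditions the
femur-only model reaches a cross-validated MAE around one third of the
predict-the-mean baseline with CCC around 0.9, and middle fusion improves
on the best single bone — the same qualitative ordering the full-size
method reports.

Other numerical details, fixed and documented: batch-norm momentum 0.1,
eps 1e-5, statistics frozen at evaluation; He-normal weight init, seeded
through R's RNG (builds and runs are bit-reproducible on one machine);
DICOM write quantizes HU to signed 16-bit stored values, so a round trip is
exact to `|slope|/2`; trilinear resampling aligns grids at the centre of
voxel (0,0,0); crops at evaluation are centred and deterministic.

## Limitations

* The DICOM layer supports the explicit-VR little-endian CT profile it
  writes (plus thickness inference); compressed transfer syntaxes and
  multi-energy CT are out of scope.
* Training is single-device CPU R code. It is bit-reproducible and fast at
  desk scale, but full-size (scale = 1) training of ResNet-50 on
  112 x 112 x 112 inputs is not a realistic CPU workload.
* The anatomical localization heuristic is a fractional-height band; real
  whole-body scans would want a detector or manual boxes in the manifest.
* Hip-bone / neck-bone contamination is handled only by the component-size
  rule, mirroring the method this package implements; learned segmentation
  is explicitly out of scope.
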