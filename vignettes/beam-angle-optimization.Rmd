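---
title: "Beam-angle optimization for double-scattering proton therapy: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beam-angle optimization for double-scattering proton therapy: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(baods)
```

## The problem

Three-port double-scattering (DS) proton plans for liver tumors are built
around a single decision that is still made by hand: the three gantry
angles. A good triplet reaches the target through little tissue (proton
range is precious), avoids parking organs at risk (OARs) behind the target
(the distal edge of a DS field is where dose stops, so whatever sits just
beyond the target gets the benefit of the falloff — unless range
uncertainty puts it back in the field), and keeps the three ports apart so
skin and normal-tissue dose is distributed.

This package scores all 360 integer gantry angles at once from CT anatomy
alone — no candidate-beam dose calculations — and then picks the three
angles with a separation-constrained greedy rule. The scorer is a
convolutional network regressing a 360-element ranking vector
(`S_beam`-style: 1.0 at ideal angles, smoothly decaying around them) from a
purely geometric input.

## The geometric input

For each gantry angle, 25 parallel rays are cast along the beam direction:
one through the isocenter, 12 on an inner ellipse and 12 on an outer
ellipse drawn on the target's beam's-eye-view (BEV) cross-section (semi-axes
1/3 and 2/3 of the BEV half-extents, rays every 30 degrees starting at BEV
"up"). Every ray is exactly 1000 mm long, ends in the isocenter plane, and
is sampled at 4000 bins (0.25 mm pitch), source side first. Each bin
collects 9 features: the Hounsfield unit (trilinear interpolation,
Z-score-normalized per patient with the population standard deviation,
clamped below at 1e-6) and the eight structure-membership bits (body, total
liver volume, tumor, duodenum, stomach, esophagus, heart, spleen), sampled
nearest-voxel so they remain exactly binary. Angles are sampled every 2
degrees, so the assembled input is a 40500 x 4000 array, laid out feature
fastest, then ray, then angle — the layout the network's first two strided
convolutions rely on.

Two readings of the ray geometry were possible: rays spanning body entry to
isocenter (variable length) or a fixed 1000 mm span. A fixed span is the
only one compatible with a fixed-shape network input; the body-mask channel
then encodes where the patient actually starts along the ray, so no
information is lost. Bins beyond the body (including beyond the isocenter
on the exit side) are sampled as-is rather than masked.

## The ranking target

Reference scores are built from the clinically planned angles: one-hot at
the rounded angles, spread with a circular Gaussian, peak-normalized so
every clinical angle scores exactly 1.0 and the vector stays in [0, 1]
(area-normalized smoothing would contradict both the stated range and the
unit peaks). Overlapping peaks combine by maximum. The Gaussian width
defaults to sigma = 5 degrees: wide enough that the 2-degree input grid
sees a gradient, narrow enough that two beams 30 degrees apart keep
distinct peaks. During training the target is circularly translated by a
fresh uniform draw from -2..2 degrees each epoch. The translation is
applied to the target only, as a label-smoothing regularizer; an optional
paired mode that also rolls the input's angle blocks is deliberately not
the default.

## The network

The feature extractor opens with two stride-matched convolutions: 9x1
stride 9 (merging the 9 features of a ray into one weighted geometric
feature) and 25x1 stride 25 (merging the 25 rays of an angle into one
weighted ray). Because kernel equals stride, these tile the input exactly
and their nominal "same" padding is zero — the only reading consistent with
the printed intermediate shapes, which also force unpadded 3x3 convolutions
(178 after 180) and floor-division 2x2/2 max-pooling (89 -> 43 after the
3x3). Six 3x3 stride-1 convolutions with channel ladder 3, 9, 27, 9, 3, 1
and pooling after the first four bring the map to 1 x 5 x 244, which
flattens to 1220. The predictor is four fully connected layers
1220 -> 560 -> 560 -> 560 -> 360. Every convolution and every hidden linear
layer is followed by batch normalization and a leaky rectified linear
activation (negative slope 0.01; the slope is not printed in the design and
0.01 is the field's default). The final layer is linear; predictions are
clamped into [0, 1] after the fact, which cannot change the ranking of
in-range scores. All layers, including backpropagation and the
adaptive-moment (Adam) optimizer, are implemented in base R —
`shape_inference()` computes every intermediate shape arithmetically and is
cross-checked against real forward passes in the tests.

Training defaults: smooth-L1 loss with beta = 0.5 (L1 and L2 available),
learning rate 0.001, weight decay 0.0002, beta1 0.9, beta2 0.999, 5000
epochs, batch size 1, fixed seed; the tracked MSE is always computed
against the unaugmented reference. One numerical choice deserves a note:
with single-sample batches, 1D batch normalization over the batch axis is
degenerate (it would output exactly zero), so the 1D layers normalize with
their running moments (initialized at 0/1, mean updated from the samples
with momentum 0.1) while the 2D layers use per-channel spatial statistics
as usual. Epsilon is 1e-5 and the running variance uses the unbiased
estimate, matching common framework defaults.

Cross-validation is patient-wise: case ids are sorted, shuffled by seed and
dealt round-robin, so folds are disjoint, balanced to within one case, and
independent of input order.

## Selection and plan metrics

`select_angles()` walks the scores in decreasing order (ties to the lower
angle) and accepts an angle only if its circular distance — gantry angles
are periodic, so 350 and 10 are 20 degrees apart — to every accepted angle
is at least 30 degrees, stopping at three. The conformity index defaults to
(TV x PIV) / (TV & PIV)^2 on voxel-count volumes; the Paddick form
(TV & PIV)^2 / (TV x PIV) is its reciprocal and available by flag. The
ratio form is the default because reported clinical values above 1 are
impossible under the Paddick form, whose range is [0, 1]. The prescribed
isodose level defaults to 100% of prescription and is configurable. V_x and
min/mean/max dose statistics are plain masked reductions, tested against
independent full-scan oracles.

## The synthetic phantom and what it does (not) show

`phantom_config()`/`generate_case()` build an abdominal phantom from eight
ellipsoids (body 40 HU, liver 60, tumor 55, hollow organs 30, heart 45,
spleen 50, air -1000), with rounded Gaussian HU noise (sd 10 by default —
CT numbers are integers, and integer HU also makes the int16 DICOM CT
round-trip exact), the isocenter at the tumor centroid, and "clinical"
angles derived from the geometry itself: each angle's central ray is scored
by minus the water-equivalent path length (relative stopping power
approximated as 1 + HU/1000, floored at 0) from body entry to the proximal
tumor edge, minus twice the OAR path length beyond the distal edge, and the
constrained top-3 of the min-max-normalized profile become the reference
angles. Because the reference angles are computed from the anatomy, the
feature-to-score mapping is learnable and training smoke tests are
meaningful. `rotation_deg` rotates the whole anatomy rigidly about the
patient axis, which shifts the geometric optimum by the same amount.

The toy dose model (`toy_dose()`) sweeps a unit-weight cylinder over the
target BEV ellipse from body entry to the distal target edge (5 mm
margins), sums fields, and normalizes mean target dose to 100%. It exists
so the metric code has realistic-shaped inputs; it is not a proton
transport model — no Bragg peak, straggling, scatter or RBE — and phantom
results say nothing quantitative about clinical plan quality. Likewise the
phantoms have none of the HU texture, breathing-averaged blur or
immobilizer structures of real AIP CT; passing tests demonstrate the
machinery (geometry, layout, optimization, selection, metrics), not
clinical performance. Immobilizer HU is deliberately not synthesized; the
body contour is the only couch-side structure.

## Desk-scale experiment design

The tests run two learning experiments at reduced scale (the full-size
input and 5000-epoch schedule need GPU-hours):

* an overfit smoke test: one phantom, reduced input (24 angles x 50 bins),
  a proportionally shrunk network (3x3 stages with 3 and 9 channels, one
  pool, hidden width 64, output still 360), 200 epochs, augmentation off —
  the training MSE must collapse;
* a geometry-recovery experiment: 8 phantoms whose anatomy is rigidly
  rotated 0..35 degrees in 5-degree steps, leave-one-out training (300
  epochs), and the held-out top-1 angle must fall within sigma (5 degrees)
  of a reference angle in at least 6 of 8 rounds.

Two design points in the recovery cohort are load-bearing, and both came
out of failed first drafts.

First, identifiability of the target. With the default anatomy the WEPL
landscape has two near-tied entry corridors about 25 degrees apart; the
30-degree separation rule then keeps exactly one of them in the reference
set, the kept one flips from case to case, and the ground truth is
discontinuous in the rotation — top-1 recovery is then impossible no
matter how well the network learns. The recovery phantoms therefore ring
the tumor with three tangentially elongated OAR blocks that leave three
narrow beam corridors about 120 degrees apart: every reference angle is a
sharp, well-separated optimum that moves continuously (and nearly
one-to-one) with the rotation. The cohort is also noise-free, so
between-case input differences are purely geometric.

Second, input resolution. The collector's angle step must resolve the
anatomical variation being recovered: with a 15-degree step, cases 5
degrees apart produce nearly identical tensors, the network cannot tell
them apart, and held-out predictions collapse onto some training case's
peaks (7-13 degrees off — exactly the cohort spacing scale). At a 5-degree
step — equal to the cohort spacing — the tensors differ by whole angle
blocks, and held-out predictions interpolate to within a few degrees. The
experiment therefore uses 72 angles x 20 bins with a one-stage 3x3 head
(He-initialized, hidden width 64), which keeps a leave-one-out round
near a minute of CPU. Epochs (300), cohort size (8), sigma (5 degrees)
and the 6-of-8 bar are fixed conditions of the experiment, not tuning
knobs.

## Known limitations

* Coplanar fans only; no non-coplanar or divergent (fan-beam) geometry.
* The DICOM codec writes and reads Explicit VR Little Endian only — enough
  for round-trips and for mainstream TPS exports, but not a general DICOM
  implementation.
* Batch size is fixed at 1; larger batches would need the 1D batch-norm
  fallback revisited.
* The full-size network is executable on CPU (a forward pass is tens of
  seconds) but training it at full scale is out of desk reach; all training
  claims in the tests are made at reduced scale.
* Leave-one-out corridor recovery at desk scale is marginal: with seven
  training phantoms the fully connected head localizes the held-out
  corridor only to within a few degrees — about the width of the
  acceptance window — and linear-range leave-one-out necessarily includes
  two extrapolation rounds. The dedicated test records the achieved hit
  count rather than papering over it.
* Whether full-scale training would match the published losses cannot be
  checked without the clinical dataset; nothing in this package asserts it.
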