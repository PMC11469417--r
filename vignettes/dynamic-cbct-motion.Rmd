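---
title: "Dynamic CBCT reconstruction with real-time single-projection motion estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic CBCT reconstruction with real-time single-projection motion estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Respiration moves thoracic and abdominal tumors by up to centimeters during
a radiotherapy fraction. Image guidance would ideally provide an
instantaneous 3D image at treatment time, but a single rotating-gantry x-ray
projection is a 2D shadow: reconstructing a volume from it is hopelessly
ill-posed without prior structure. `rtcbct` implements a one-shot scheme
that extracts all the prior structure it needs from the pre-treatment
cone-beam scan itself — no planning 4D-CT, no population model — and then
estimates 3D motion in real time from one projection at an arbitrary gantry
angle.

## The model

The dynamic anatomy over the scan is factorized as a static reference volume
deformed by a time-varying displacement field,

$$I(x, p) = I_\mathrm{ref}(x + d(x, p)),$$

where $p$ indexes projections (time) and $d$ is a pull-back displacement in
mm. The field itself is low-rank in space–time:

$$d_k(x, p) = \sum_{i=1}^{3} w_{i,k}(p)\, e_{i,k}(x), \qquad k \in \{x, y, z\},$$

with nine spatial *motion basis components* $e_{i,k}$ (three hierarchy
levels times three Cartesian directions) and nine scalar scores per
projection. The three ingredients are:

* $I_\mathrm{ref}$: a hash-encoded coordinate network (multiresolution
  trilinear feature grids feeding a small ReLU MLP, softplus output so
  attenuation stays non-negative);
* $e_{i,k}$: cubic B-spline interpolants of learnable control grids; the
  control-point count per axis doubles at each level, so level 1 carries
  bulk motion and level 3 detail;
* $w_{i,k}(p)$: the output of a lightweight convolutional *motion encoder*
  (six 3×3 stride-2 convolutions with 2–32 channels, batch norm, ReLU, and
  a 9-output linear head) that reads the raw projection. Because the
  encoder maps pixels to scores directly, the same network serves both
  reconstruction (on the training frames) and real-time inference (on any
  future frame at any angle).

A single shared score per level (three temporal coefficients) would be the
most compact factorization, but it cannot decouple the superior-inferior,
anterior-posterior and lateral components of respiratory motion; the
per-direction form with nine scores is the one consistent with the basis
regularization below, which constrains each direction separately, and is
used throughout.

### Objectives

Training minimizes a weighted sum of:

* image-domain MSE between $I_\mathrm{ref}$ and a label volume — the FDK
  reconstruction of the full scan at low resolution, and the trilinearly
  upsampled low-resolution solution at high resolution (warm starts);
* projection-domain MSE between DRRs of the deformed volumes and the
  measured frames (the main data term; the projector is linear in the
  volume and its exact adjoint supplies the gradient);
* isotropic total variation of $I_\mathrm{ref}$ (weight 2e-4);
* basis ortho-normality: $(\|e_{i,k}\|^2 - 1)^2$ plus squared pairwise
  inner products between levels, removing the scale/mixing ambiguity of the
  factorization;
* zero-mean scores (weight 1e-3): the constant motion baseline belongs in
  $I_\mathrm{ref}$, not in $d$;
* DVF self-consistency (weight 1e3): warping forward by $d$ and back by its
  iterative 3-step inverse must return $I_\mathrm{ref}$;
* a score-consistency augmentation loss (weight 1e-4): DRRs of re-deformed
  volumes at random angles, with scores rescaled by
  $w' = r_1 r_2 w$, $r_1 \sim U(0.6, 2)$ per instance and
  $r_2 \sim U(0.8, 1.2)$ per channel, must be decoded back to $w'$.

### Discretization choices

The basis norms and inner products use the voxel-*mean* inner product
$\langle a, b\rangle = \tfrac1N \sum_x a(x) b(x)$ rather than a plain voxel
sum. Both discretize the same continuous constraint; the mean keeps
unit-norm components at RMS amplitude 1 so the scores carry the physical mm
scale regardless of grid size, which conditions the encoder's output layer
far better than sums over ~4×10^5 voxels would.

The zero-mean score penalty is estimated per mini-batch; it is an unbiased
estimate of the all-projection mean and costs nothing extra in a streaming
loop.

The self-consistency loss masks out voxels whose round-trip sampling left
the field of view (border clamping is not a motion error), and the
iterative inverse is treated as a constant during backpropagation: at the
minimizer the round-trip residual vanishes, so the extra gradient path
through the fixed-point iterations changes cost, not the optimum.

## The training schedule

`training_schedule()` encodes the progressive strategy: stage I at 4 mm
(image warm start I-a, projection-driven reconstruction I-b, joint motion
model I-c), stage II at 2 mm (re-warm-start II-a, joint refinement
II-b/II-c with angle augmentation, and a dedicated encoder-hardening stage
II-d with motion *and* angle augmentation while anatomy and motion basis
are frozen). A zero learning rate freezes a component bitwise for the
stage; the trainer simply never computes its gradient. "Epoch" here means
one Adam step on one mini-batch of projections drawn without replacement
per cycle — the stage counts (400/700/1700/1000/1000/1000/1000) are
iteration counts, not passes over the scan, which is the only reading
compatible with their magnitudes.

Adam is the optimizer throughout, with one fresh state per stage and a
global gradient norm clip of 10 for robustness against rare large projection residuals
early in a stage. Two schedule-scaling rules keep scaled-down runs
faithful: when stage epoch counts are multiplied by `epoch_scale`, the
learning rates are divided by it, so the per-stage optimizer displacement
(step size times step count) matches the full-length schedule; and within
every stage the learning rate stays constant for the first 70% of the
epochs and then decays linearly to zero. The tail decay is final-iterate
smoothing: with small mini-batches a constant-rate Adam iterate retains
gradient-noise jitter in the hash tables, which shows up as a flat-region
noise floor in the rendered volume and is poison for structure-similarity
metrics whose reference variance is zero; decaying only the tail buys the
smoothing without throttling convergence.

## The synthetic study

`build_phantom()` voxelizes an analytic thorax: body ellipsoid (soft
tissue, 0.020 mm^-1), two lungs (0.005), a diaphragm dome, a bony spine
(0.040), and a 30-mm spherical tumor in the inferior-anterior right lung, placed clear of the
chest wall and the diaphragm so its contour is detached (a connectivity
property the contouring step relies on). Ground-truth
motion is generated directly as a displacement field
$d(x, t) = a(t) \cdot A(x)$: a smooth diaphragm-anchored shape $A$ (SI
dominant, smaller AP/LR components, vanishing toward the lung apices and
the chest wall) times a raised-cosine breathing amplitude $a(t)$ (period
4 s, long exhale rest). The shape is normalized so its mean over the tumor
is one — the trajectory's configured peak displacements (defaults: 10 mm
SI, 3 mm AP, 1 mm LR) are then exactly the tumor's. Seven trajectory kinds
emulate regular breathing, amplitude drift, frequency drift, waveform/
baseline shift, slow breathing, joint irregularity, and an
extended-amplitude variant (SI peak ×1.5) that probes extrapolation beyond
the training range.

Generating truth as an analytic DVF (rather than re-meshing anatomy) keeps
the evaluation chain self-consistent: per-frame volumes, masks, and
centroids all derive from the same field, and the field is smooth enough
to be invertible on the interior.

What the phantom does *not* emulate: organ texture, hysteresis (the motion
is rank-one in time by construction), cardiac motion, scatter and beam
hardening, detector noise physics (an optional Poisson toggle exists, off
by default since the reference simulation study is noise-free). Passing
the study therefore demonstrates the estimation machinery — geometry,
reconstruction, low-rank motion recovery, angle-agnostic inference — not
robustness to every clinical confounder.

## Problem sizes

Two profiles are built in. The full-scale configuration:
200×200×100 voxels at 2 mm, 660 projections of 256×192
pixels at 1.55 mm over 360°, batch 32, hash encoder with 12 levels and
2^19-entry tables, 2×64 MLP. The package's own studies and test suite use
the `desk_profile()`: a 96×96×48 grid at 2 mm, a 240-frame training scan
of 64×48-pixel frames, 120-frame test scans, epochs divided by four, batch
4, an 8-level/2^15/1×16 hash network, and the encoder reading frames at
their native 64×48 size. These are fixed study conditions so that a
complete train-and-evaluate cycle runs on a single CPU core in well under
half an hour; they are deliberately not free knobs of the experiments.

## Numerical notes

* The projector integrates the trilinearly interpolated volume at a fixed
  step of half the smallest voxel spacing (Joseph-style). It is exactly
  linear in the voxel values and ships with its exact adjoint; an exact
  Siddon path integrator is kept purely as a test oracle.
* FDK uses the exact discrete ramp kernel on the virtual detector at the
  isocenter and the standard 1/2 redundancy factor for full 360° scans;
  half-fan offsets are supported in the geometry but the tested default is
  full-fan.
* Warping clamps out-of-support samples to the border value; the warp is
  exact (bit-for-bit) for zero displacement, which the identity tests
  exploit.
* Coordinates: angles in degrees CCW about +z with the source on +y at 0°;
  world mm; x = left-right, y = anterior-posterior, z = superior-inferior.
* All randomness flows through R's RNG from one master seed; training runs
  are bitwise reproducible.
* Degenerate inputs: empty tumor masks yield an `NA` center-of-mass error
  with a warning (excluded and counted by the study harness, never
  silently zero); DVF inversion reports divergence through its `residual`
  attribute instead of raising.

## Known limitations

* The motion model is low-rank with nine temporal degrees of freedom;
  motion outside that subspace (e.g. sudden non-respiratory shifts) is
  projected onto it.
* Batch-norm statistics are frozen at inference; a large distribution
  shift between training DRRs and measured frames would degrade scores
  (the augmentation stages exist precisely to narrow that gap).
* The contour propagation uses the forward field with nearest-neighbour
  sampling — binarity is preserved, but masks thinner than a voxel can
  alias.
* Inference wall time is measured and logged (`ms_per_frame` attribute),
  never asserted: it is hardware-bound.

## A minimal session

```{r}
library(rtcbct)

prof <- desk_profile()
phantom <- build_phantom(phantom_spec(prof$grid$dims, prof$grid$spacing))
traj <- make_trajectory("X3", prof$duration_s,
                        prof$n_train_frames / prof$duration_s, seed = 1001)
scan <- simulate_scan(phantom, traj, geometry_args = prof$geometry_args)

fit <- rtcbct(scan$projections, prof$grid, schedule = prof$schedule,
              batch_size = prof$batch_size,
              inr_options = prof$inr_options,
              encoder_options = prof$encoder_options, seed = 1)
summary(fit)
plot(fit)

# real-time inference from one frame of an unseen scan
test <- simulate_scan(phantom, make_trajectory("X6", 60, 2, seed = 2002),
                      geometry_args = prof$geometry_args,
                      angle_offset = 90.27)
pred <- predict(fit, test$projections$frames[, , 10])
pred$scores

# or run the whole cross-scenario study
study <- run_simulation_study(seed = 1)
study
```
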