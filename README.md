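# rtcbct

Real-time volumetric imaging during radiotherapy from a single x-ray
projection — without patient-specific prior models.

A cone-beam CT (CBCT) scanner acquires a rotating sequence of 2D x-ray
projections. Conventional reconstruction needs hundreds of them, so it
cannot follow respiratory motion; a single projection is fast but is only a
2D shadow. `rtcbct` implements a one-shot, dual-task scheme around this
dilemma:

1. **Dynamic reconstruction.** From one standard pre-treatment scan it
   jointly estimates a static reference anatomy
   $I_\mathrm{ref}(x)$ — a hash-encoded implicit neural representation —
   and a data-driven low-rank motion model: the dynamic anatomy is
   $I(x,p) = I_\mathrm{ref}(x + d(x,p))$ with
   $d_k(x,p) = \sum_{i=1}^{3} w_{i,k}(p)\, e_{i,k}(x)$, where the
   $e_{i,k}$ are three hierarchy levels of learnable cubic-B-spline motion
   basis components per Cartesian direction.
2. **Real-time motion estimation.** A lightweight CNN *motion encoder* is
   trained alongside so that at treatment time one projection at an
   arbitrary gantry angle yields the nine scores $w_{i,k}$ — hence a dense
   displacement field, a volumetric image, and a propagated tumor contour —
   in milliseconds.

Training is driven by projection-domain similarity between digitally
reconstructed radiographs (DRRs) of the deformed volumes and the measured
frames, regularized by total variation, basis ortho-normality, zero-mean
scores and displacement-field self-consistency, and hardened by motion/angle
augmentation in a progressive two-resolution schedule. Everything — the
differentiable cone-beam projector with exact adjoint, FDK warm start,
B-spline motion basis, hash-encoded coordinate network, CNN encoder, and
the staged trainer — is implemented in this package (R with Rcpp kernels).

The package also ships an analytic dynamic thorax phantom with ground-truth
displacement fields (seven breathing scenarios emulating regular, drifting,
irregular, and extended-amplitude motion), and the evaluation suite used in
the simulation studies: relative error, volumetric SSIM, tumor
center-of-mass error (COME), Dice coefficient (DSC), and Amsterdam-Shroud
respiratory traces.

## Worked example

Simulate a pre-treatment scan of the moving phantom, train the joint model,
and infer motion from single projections of an unseen scan at unseen angles:

```r
library(rtcbct)

prof <- desk_profile()      # 96x96x48 @ 2 mm study profile
phantom <- build_phantom(phantom_spec(prof$grid$dims, prof$grid$spacing))
traj <- make_trajectory("X3", prof$duration_s,
                        prof$n_train_frames / prof$duration_s, seed = 1001)
scan <- simulate_scan(phantom, traj, geometry_args = prof$geometry_args)

fit <- rtcbct(scan$projections, prof$grid, schedule = prof$schedule,
              batch_size = prof$batch_size, inr_options = prof$inr_options,
              encoder_options = prof$encoder_options, seed = 1)

# real-time inference: one frame in, scores / DVF / volume out
test <- simulate_scan(phantom, make_trajectory("X6", 60, 2, seed = 2002),
                      geometry_args = prof$geometry_args,
                      angle_offset = 90.27)
pred <- predict(fit, test$projections$frames[, , 10])
str(pred$scores)

# the full cross-scenario study: train on X3, test on X1..X7 at offset angles
study <- run_simulation_study(seed = 1)
study
```

The study print-out reports, per test scenario and overall, the mean tumor
center-of-mass error (mm), Dice coefficient of the propagated contour, SSIM
and relative error of the solved real-time volumes. On the desk profile
(seed 1) it prints:

```
Simulation study: trained on X3, tested on 7 scenarios
 scenario come_mean come_sd dsc_mean ssim_mean re_mean n_empty
       X1     1.451  0.5660   0.9105    0.7403  0.1742       0
       X2     1.587  0.9523   0.9027    0.7388  0.1755       0
       X3     1.529  0.6205   0.9056    0.7392  0.1747       0
       X4     1.629  0.9378   0.8996    0.7429  0.1720       0
       X5     1.556  0.6953   0.9023    0.7392  0.1740       0
       X6     1.560  0.7882   0.9036    0.7392  0.1750       0
       X7     2.437  2.6996   0.8653    0.7269  0.1874       0

overall: COME 1.68 +- 1.28 mm | DSC 0.899 | SSIM 0.7381 | RE 0.176
```

COME is the 3D distance between the propagated contour's centroid and the
ground-truth tumor centroid — the headline tracking accuracy (1.7 mm here,
sub-voxel on the 2 mm grid and well inside the ~3.1 mm detector sampling at
the isocenter); DSC measures contour overlap; SSIM and relative error score
the solved volumes against the analytically deformed ground-truth phantom.
The extended-amplitude scenario X7 probes motion beyond the training range
and is, as expected, the hardest row.

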