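#' Analytic dynamic thorax phantom specification
#'
#' A thorax-like attenuation phantom assembled from analytic shapes: a body
#' ellipsoid of soft tissue, two lung ellipsoids of low attenuation, a
#' diaphragm dome intruding into each lung base, a bony spine cylinder, and a
#' spherical lung tumor (default 30 mm diameter) in the lower lobe of the
#' right lung. All structure sizes scale with the grid extent, so the same
#' specification serves the full 200x200x100 grid and scaled-down grids.
#'
#' Attenuation values (mm^-1) are of kilovoltage-CT magnitude: soft tissue
#' 0.02, lung 0.005, bone 0.04, tumor 0.02.
#'
#' @param dims Grid dimensions (voxels).
#' @param spacing Voxel size (mm).
#' @param tumor_diameter Tumor diameter (mm); 0 gives an empty mask.
#' @param attenuation Named values for tissue, lung, bone, tumor (mm^-1).
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(200L, 200L, 100L), spacing = c(2, 2, 2),
                         tumor_diameter = 30,
                         attenuation = c(tissue = 0.020, lung = 0.005,
                                         bone = 0.040, tumor = 0.020)) {
  if (any(attenuation < 0)) stop("attenuations must be >= 0")
  structure(list(grid = grid_def(dims, spacing),
                 tumor_diameter = tumor_diameter,
                 attenuation = attenuation), class = "phantom_spec")
}

#' Build the thorax phantom
#'
#' Deterministic voxelization of a [phantom_spec()]: returns the static
#' attenuation volume, the binary tumor mask, and the normalized motion-shape
#' field used to generate ground-truth displacement fields. The motion shape
#' is a smooth diaphragm-anchored field: its superior-inferior component is 1
#' near the diaphragm and decays to zero toward the lung apices and the chest
#' wall, with smaller anterior-posterior and lateral components; multiplying
#' it by a breathing amplitude and per-direction peak displacements yields an
#' analytically known (and, in the contractive regime, invertible) DVF for
#' every time point.
#'
#' @param spec A [phantom_spec()].
#' @return List with `volume` ([volume_grid()]), `tumor_mask`
#'   ([volume_grid()], 0/1), `motion_shape` (matrix `n_voxels x 3`, unit
#'   peak), `spec`.
#' @export
build_phantom <- function(spec) {
  gd <- spec$grid
  att <- spec$attenuation
  ext <- (gd$dims - 1) * gd$spacing
  hx <- ext[1] / 2; hy <- ext[2] / 2; hz <- ext[3] / 2
  xs <- gd$origin[1] + (seq_len(gd$dims[1]) - 1) * gd$spacing[1]
  ys <- gd$origin[2] + (seq_len(gd$dims[2]) - 1) * gd$spacing[2]
  zs <- gd$origin[3] + (seq_len(gd$dims[3]) - 1) * gd$spacing[3]
  cx0 <- mean(range(xs)); cy0 <- mean(range(ys)); cz0 <- mean(range(zs))
  X <- array(rep(xs, times = gd$dims[2] * gd$dims[3]), gd$dims) - cx0
  Y <- array(rep(rep(ys, each = gd$dims[1]), times = gd$dims[3]), gd$dims) - cy0
  Z <- array(rep(zs, each = gd$dims[1] * gd$dims[2]), gd$dims) - cz0

  vol <- array(0, gd$dims)
  # body
  ab <- 0.92 * hx; bb <- 0.85 * hy; cb <- 1.6 * hz
  body <- (X / ab)^2 + (Y / bb)^2 + (Z / cb)^2 <= 1
  vol[body] <- att[["tissue"]]
  # lungs (right lung at +x)
  al <- 0.34 * hx; bl <- 0.55 * hy; cl <- 0.62 * hz
  lung_cz <- 0.18 * hz
  lungs <- array(FALSE, gd$dims)
  for (sgn in c(-1, 1)) {
    lcx <- sgn * 0.42 * hx
    lung <- ((X - lcx) / al)^2 + (Y / bl)^2 + ((Z - lung_cz) / cl)^2 <= 1
    # diaphragm dome: a tissue sphere pushing into the lung base, kept
    # clear of the tumor so the contour stays detached
    dome <- ((X - lcx)^2 + Y^2 + (Z - (lung_cz - 1.55 * cl))^2) <=
      (0.8 * cl)^2
    lung <- lung & !dome
    lungs <- lungs | lung
  }
  vol[lungs & body] <- att[["lung"]]
  # spine
  spine <- (X^2 + (Y - 0.55 * hy)^2) <= (0.10 * min(hx, hy) * 2)^2 &
    abs(Z) <= 0.95 * hz
  vol[spine & body] <- att[["bone"]]
  # tumor: inferior-anterior part of the right lung, detached from the
  # chest wall and the diaphragm
  tumor_center <- c(0.42 * hx, -0.15 * hy, lung_cz - 0.15 * cl)
  r <- spec$tumor_diameter / 2
  tumor <- ((X - tumor_center[1])^2 + (Y - tumor_center[2])^2 +
              (Z - tumor_center[3])^2) <= r^2
  vol[tumor] <- att[["tumor"]]

  # motion shape: superior decay from the diaphragm, vanishing at chest wall
  sstep <- function(s) { s <- pmin(pmax(s, 0), 1); s * s * (3 - 2 * s) }
  z_apex <- lung_cz + cl
  z_dia <- lung_cz - 0.62 * cl
  wz <- sstep((z_apex - Z) / (z_apex - z_dia))
  rho <- sqrt((X / ab)^2 + (Y / bb)^2)
  wr <- sstep((1 - rho) / 0.35)
  W <- wz * wr
  # normalize so the mean shape amplitude over the tumor is 1: the
  # trajectory's peak displacements then are the tumor's displacements
  if (any(tumor)) W <- W / mean(W[tumor])
  shape <- cbind(as.numeric(W * X / hx),   # lateral, outward-proportional
                 as.numeric(-W),           # anterior-posterior
                 as.numeric(W))            # superior-inferior (dominant)

  list(volume = volume_grid(vol, gd$spacing, gd$origin),
       tumor_mask = volume_grid(tumor * 1, gd$spacing, gd$origin),
       motion_shape = shape, spec = spec)
}

#' Respiratory motion trajectory
#'
#' A breathing amplitude trace `a(t)` built from a raised-cosine waveform
#' (`((1 - cos(2 pi t / T)) / 2)^2`, period 4 s by default: long exhale rest,
#' brief inhale peak) modulated per scenario, plus per-direction peak
#' displacements. The seven kinds emulate a spectrum of motion scenarios:
#'
#' * `regular` (X1): fixed period and amplitude.
#' * `amp` (X2): cycle-to-cycle amplitude variation.
#' * `freq` (X3): slowly drifting breathing frequency.
#' * `pattern` (X4): drifting waveform shape and baseline.
#' * `slow` (X5): 1.5x longer period.
#' * `irregular` (X6): joint amplitude and frequency irregularity.
#' * `extended` (X7): amplitude-varying with the superior-inferior peak
#'   scaled beyond the other scenarios' range (tests extrapolation).
#'
#' @param kind Scenario name (`"regular"`, ..., `"extended"`) or alias
#'   `"X1"`..`"X7"`.
#' @param duration_s Scan duration (s).
#' @param fps Frames per second.
#' @param seed Optional seed making the stochastic envelopes reproducible
#'   without disturbing the caller's RNG stream.
#' @param period Base breathing period (s).
#' @param si_peak,ap_peak,lr_peak Peak displacements (mm) at unit amplitude.
#' @param extended_factor SI-range extension for `kind = "extended"`.
#' @return Object of class `motion_trajectory` with fields `t`, `a`,
#'   `si_peak`, `ap_peak`, `lr_peak`, `kind`.
#' @export
make_trajectory <- function(kind = "regular", duration_s = 60, fps = 11,
                            seed = NULL, period = 4,
                            si_peak = 10, ap_peak = 3, lr_peak = 1,
                            extended_factor = 1.5) {
  aliases <- c(X1 = "regular", X2 = "amp", X3 = "freq", X4 = "pattern",
               X5 = "slow", X6 = "irregular", X7 = "extended")
  if (kind %in% names(aliases)) kind <- aliases[[kind]]
  kind <- match.arg(kind, unname(aliases))
  n <- round(duration_s * fps)
  t <- (seq_len(n) - 1) / fps
  base <- function(ph) ((1 - cos(ph)) / 2)^2
  a <- with_seed(seed, {
    switch(kind,
      regular = base(2 * pi * t / period),
      slow = base(2 * pi * t / (1.5 * period)),
      amp = {
        env <- 1 + 0.25 * sin(2 * pi * t / 17) + smooth_noise(t, 0.10)
        pmin(pmax(env, 0.4), 1.25) * base(2 * pi * t / period)
      },
      freq = {
        inst_T <- period * (1 + 0.2 * sin(2 * pi * t / 23))
        base(cumsum(2 * pi / (inst_T * fps)))
      },
      pattern = {
        ex <- 2 + sin(2 * pi * t / 25)
        drift <- 0.08 * (1 + sin(2 * pi * t / 30))
        ((1 - cos(2 * pi * t / period)) / 2)^ex + drift
      },
      irregular = {
        inst_T <- period * (1 + 0.15 * sin(2 * pi * t / 19) +
                              smooth_noise(t, 0.08))
        inst_T <- pmax(inst_T, 0.5 * period)
        env <- 1 + 0.2 * sin(2 * pi * t / 13) + smooth_noise(t, 0.08)
        pmin(pmax(env, 0.4), 1.25) * base(cumsum(2 * pi / (inst_T * fps)))
      },
      extended = {
        env <- 1 + 0.15 * sin(2 * pi * t / 15) + smooth_noise(t, 0.05)
        pmin(pmax(env, 0.5), 1.15) * base(2 * pi * t / period)
      })
  })
  if (kind == "extended") si_peak <- si_peak * extended_factor
  structure(list(t = t, a = as.numeric(a), fps = fps,
                 duration_s = duration_s, period = period, kind = kind,
                 si_peak = si_peak, ap_peak = ap_peak, lr_peak = lr_peak),
            class = "motion_trajectory")
}

#' @export
print.motion_trajectory <- function(x, ...) {
  cat(sprintf(paste0("Motion trajectory '%s': %d frames over %.0f s, ",
                     "peaks SI %.1f / AP %.1f / LR %.1f mm\n"),
              x$kind, length(x$a), x$duration_s, x$si_peak, x$ap_peak,
              x$lr_peak))
  invisible(x)
}

# smooth random envelope: spline through sparse normal knots
smooth_noise <- function(t, sd) {
  nk <- max(4, ceiling(max(t) / 5))
  kt <- seq(min(t), max(t), length.out = nk)
  kv <- rnorm(nk, 0, sd)
  spline(kt, kv, xout = t)$y
}

# run code under a temporary seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv()))
  force(code)
}

# ground-truth DVF of frame i: a(t_i) * shape * diag(peaks)
truth_dvf_matrix <- function(phantom, trajectory, i) {
  peaks <- c(trajectory$lr_peak, trajectory$ap_peak, trajectory$si_peak)
  phantom$motion_shape * rep(trajectory$a[i] * peaks,
                             each = nrow(phantom$motion_shape))
}

#' Simulate a dynamic cone-beam scan of the phantom
#'
#' For every frame, the static phantom is deformed by the analytic
#' ground-truth DVF of that time point and projected at the frame's gantry
#' angle; the tumor mask is propagated alongside. Angles cover 360 degrees
#' uniformly, optionally offset (the disjoint-angle test protocol uses an
#' offset of 90.27 degrees so that no test frame shares angle and motion
#' state with a training frame).
#'
#' @param phantom Result of [build_phantom()].
#' @param trajectory A [make_trajectory()]; its length sets the frame count.
#' @param geometry_args Named list of [scan_geometry()] arguments (everything
#'   but `angles`/`frame_rate`); defaults to the full-scale detector (256x192
#'   px at 1.55 mm, SAD 1000 mm, SDD 1500 mm).
#' @param angle_offset Added to all gantry angles (degrees).
#' @param noise `"none"` or `"poisson"` (photon noise on the pre-log
#'   intensities with `i0` incident photons).
#' @param i0 Incident photon count for Poisson noise.
#' @param step_rel Projector sampling step (relative to voxel size).
#' @return Object of class `cbct_sim`: `projections` ([projection_set()]),
#'   `truth` (per-frame amplitude `a`, tumor centers `centers` (3 x Np),
#'   trajectory, phantom).
#' @export
simulate_scan <- function(phantom, trajectory,
                          geometry_args = list(sad = 1000, sdd = 1500,
                                               n_u = 256L, n_v = 192L,
                                               du = 1.55, dv = 1.55),
                          angle_offset = 0, noise = c("none", "poisson"),
                          i0 = 1e5, step_rel = 0.5) {
  noise <- match.arg(noise)
  n <- length(trajectory$a)
  angles <- (seq_len(n) - 1) * 360 / n + angle_offset
  geom <- do.call(scan_geometry,
                  c(geometry_args, list(angles = angles,
                                        frame_rate = trajectory$fps)))
  gd <- grid_def(dim(phantom$volume$data), phantom$volume$spacing,
                 phantom$volume$origin)
  frames <- array(0, c(geom$n_v, geom$n_u, n))
  centers <- matrix(NA_real_, 3, n)
  for (i in seq_len(n)) {
    d <- dvf_fast(truth_dvf_matrix(phantom, trajectory, i), gd)
    vol <- warp_volume(phantom$volume, d)
    frames[, , i] <- forward_project(vol, geom, angles[i], step_rel)
    m <- propagate_contour(phantom$tumor_mask, d)
    centers[, i] <- mask_centroid(m)
  }
  if (noise == "poisson") {
    counts <- matrix(stats::rpois(length(frames), i0 * exp(-frames)),
                     nrow = nrow(frames))
    frames <- array(-log(pmax(counts, 1) / i0), dim(frames))
  }
  structure(list(projections = projection_set(frames, geom),
                 truth = list(a = trajectory$a, centers = centers,
                              trajectory = trajectory,
                              angle_offset = angle_offset),
                 phantom = phantom), class = "cbct_sim")
}

#' Ground-truth quantities of a simulated frame
#'
#' Reconstruct the analytic ground truth of frame `i` of a [simulate_scan()]
#' result: the displacement field, the deformed volume, or the deformed
#' tumor mask.
#'
#' @param sim A `cbct_sim`.
#' @param i Frame index.
#' @return [dvf()] / [volume_grid()].
#' @export
sim_truth_dvf <- function(sim, i) {
  gd <- grid_def(dim(sim$phantom$volume$data), sim$phantom$volume$spacing,
                 sim$phantom$volume$origin)
  dvf(truth_dvf_matrix(sim$phantom, sim$truth$trajectory, i), gd)
}

#' @rdname sim_truth_dvf
#' @export
sim_truth_volume <- function(sim, i) {
  warp_volume(sim$phantom$volume, sim_truth_dvf(sim, i))
}

#' @rdname sim_truth_dvf
#' @export
sim_truth_mask <- function(sim, i) {
  propagate_contour(sim$phantom$tumor_mask, sim_truth_dvf(sim, i))
}
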