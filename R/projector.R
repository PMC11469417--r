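#' Cone-beam forward projection (DRR generation)
#'
#' Computes the digitally reconstructed radiograph of an attenuation volume at
#' one gantry angle: each detector pixel receives the line integral of the
#' attenuation along the ray from the x-ray source to the pixel center
#' (dimensionless, since attenuation is mm^-1 and path length mm).
#'
#' The integral uses Joseph-style fixed-step sampling of the trilinearly
#' interpolated volume (step = `step_rel` times the smallest voxel spacing),
#' which makes the operator linear in the voxel values with an exact adjoint —
#' the property the training gradients rely on. [siddon_project()] offers an
#' exact-path-length alternative used as a test oracle.
#'
#' @param volume A [volume_grid()].
#' @param geometry A [scan_geometry()].
#' @param angle Gantry angle (degrees).
#' @param step_rel Sampling step relative to the smallest voxel spacing.
#' @return Matrix `(n_v, n_u)` of line integrals.
#' @export
forward_project <- function(volume, geometry, angle, step_rel = 0.5) {
  stopifnot(inherits(volume, "volume_grid"), inherits(geometry, "scan_geometry"))
  if (!is.finite(angle)) stop("'angle' must be finite")
  if (length(volume$data) == 0 || any(volume$spacing <= 0))
    stop("invalid volume: empty data or non-positive spacing")
  step <- step_rel * min(volume$spacing)
  cpp_forward_project(as.numeric(volume$data), grid_dims(volume),
                      grid_spacing(volume), grid_origin(volume),
                      geometry$sad, geometry$sdd, geometry$n_u, geometry$n_v,
                      geometry$du, geometry$dv, geometry$detector_offset_u,
                      angle, step)
}

#' Adjoint of the forward projector
#'
#' Scatters a projection-domain gradient image back into the volume along the
#' projector's exact sampling pattern; `<A v, p> == <v, At p>` holds to
#' rounding. This is the backward pass of [forward_project()] with respect to
#' the voxel values.
#'
#' @param gproj Matrix `(n_v, n_u)`: gradient w.r.t. the projection.
#' @param grid A [volume_grid()] (or grid definition) giving the target grid.
#' @inheritParams forward_project
#' @return Numeric array with the volume's dimensions.
#' @export
backproject_gradient <- function(gproj, grid, geometry, angle, step_rel = 0.5) {
  gd <- if (inherits(grid, "volume_grid"))
    grid_def(dim(grid$data), grid$spacing, grid$origin) else grid
  step <- step_rel * min(gd$spacing)
  g <- cpp_backproject_grad(gproj, gd$dims, gd$spacing, gd$origin,
                            geometry$sad, geometry$sdd, geometry$n_u,
                            geometry$n_v, geometry$du, geometry$dv,
                            geometry$detector_offset_u, angle, step)
  array(g, gd$dims)
}

#' Exact Siddon ray tracing
#'
#' Radiological path integrator that accumulates exact ray-box intersection
#' lengths through the voxel grid. Not differentiable in a useful way (the
#' weights are piecewise constant in the volume); kept as the independent
#' oracle for [forward_project()].
#'
#' @inheritParams forward_project
#' @return Matrix `(n_v, n_u)` of exact line integrals.
#' @export
siddon_project <- function(volume, geometry, angle) {
  stopifnot(inherits(volume, "volume_grid"))
  cpp_siddon_project(as.numeric(volume$data), grid_dims(volume),
                     grid_spacing(volume), grid_origin(volume),
                     geometry$sad, geometry$sdd, geometry$n_u, geometry$n_v,
                     geometry$du, geometry$dv, geometry$detector_offset_u,
                     angle)
}

#' Project a volume at every angle of a scan
#'
#' Batch wrapper over [forward_project()]: one frame per entry of
#' `geometry$angles`, in order.
#'
#' @inheritParams forward_project
#' @return A [projection_set()].
#' @export
project_set <- function(volume, geometry, step_rel = 0.5) {
  frames <- array(0, c(geometry$n_v, geometry$n_u, length(geometry$angles)))
  for (i in seq_along(geometry$angles))
    frames[, , i] <- forward_project(volume, geometry, geometry$angles[i],
                                     step_rel)
  projection_set(frames, geometry)
}

#' Feldkamp-Davis-Kress reconstruction
#'
#' Filtered backprojection for a circular cone-beam scan: cosine weighting,
#' ramp filtering on the virtual detector at the isocenter, and weighted
#' backprojection. Used to produce the approximate CBCT that warm-starts the
#' reference-anatomy network; for a full 360-degree scan every voxel is seen
#' from redundant directions, handled by the standard 1/2 factor.
#'
#' @param projections A [projection_set()].
#' @param grid Grid definition (a [volume_grid()] or the result of an internal
#'   grid spec) for the reconstruction: `dims`, `spacing`, `origin`.
#' @return A [volume_grid()] with the reconstructed attenuation.
#' @export
fdk_reconstruct <- function(projections, grid) {
  stopifnot(inherits(projections, "projection_set"))
  gd <- if (inherits(grid, "volume_grid"))
    grid_def(dim(grid$data), grid$spacing, grid$origin) else grid
  geom <- projections$geometry
  ang <- geom$angles
  span <- diff(range(ang))
  if (length(ang) < 50 || span < 200)
    warning(sprintf(paste0("FDK with %d views over %.0f deg is badly sampled; ",
                           "expect strong artifacts"), length(ang), span))
  v <- cpp_fdk_reconstruct(as.numeric(projections$frames),
                           as.integer(dim(projections$frames)), ang,
                           gd$dims, gd$spacing, gd$origin,
                           geom$sad, geom$sdd, geom$du, geom$dv,
                           geom$detector_offset_u)
  volume_grid(array(v, gd$dims), gd$spacing, gd$origin)
}

#' Discrete ramp filter kernel
#'
#' The spatial-domain ramp kernel used by [fdk_reconstruct()]:
#' `h[0] = 1/(4 du^2)`, `h[n] = -1/(pi^2 n^2 du^2)` for odd `n`, zero for even
#' `n`.
#'
#' @param n Half-width: the kernel covers lags `-n..n`.
#' @param du Detector sample spacing (mm).
#' @return Numeric vector of length `2n + 1`.
#' @export
ramp_kernel <- function(n, du) {
  as.numeric(cpp_ramp_kernel(as.integer(n), du))
}
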