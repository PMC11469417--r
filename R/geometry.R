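#' Cone-beam acquisition geometry
#'
#' Describes a circular cone-beam scan: source-to-axis and source-to-detector
#' distances, flat-panel detector layout, and the per-frame gantry angles.
#' Angles are in degrees, counter-clockwise about the superior-inferior axis,
#' with the source on the +y (anterior) axis at 0 degrees. World coordinates
#' are in mm.
#'
#' @param sad Source-to-axis distance (mm).
#' @param sdd Source-to-detector distance (mm); must exceed `sad`.
#' @param n_u,n_v Detector pixel counts (lateral, axial).
#' @param du,dv Detector pixel pitch (mm).
#' @param angles Gantry angle per projection frame (degrees).
#' @param detector_offset_u Lateral detector offset (mm); 0 for full-fan
#'   acquisition, non-zero for half-fan.
#' @param frame_rate Acquisition frame rate (frames/s).
#' @return An object of class `scan_geometry`.
#' @export
scan_geometry <- function(sad, sdd, n_u, n_v, du, dv, angles,
                          detector_offset_u = 0, frame_rate = 11) {
  stopifnot(is.numeric(sad), length(sad) == 1L, sad > 0)
  if (!(is.numeric(sdd) && sdd > sad))
    stop("'sdd' must be a number greater than 'sad'")
  stopifnot(n_u >= 1, n_v >= 1, du > 0, dv > 0)
  if (!all(is.finite(angles)) || length(angles) < 1L)
    stop("'angles' must be a non-empty finite numeric vector")
  structure(list(sad = sad, sdd = sdd, n_u = as.integer(n_u),
                 n_v = as.integer(n_v), du = du, dv = dv,
                 detector_offset_u = detector_offset_u,
                 angles = as.numeric(angles), frame_rate = frame_rate),
            class = "scan_geometry")
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf("Cone-beam scan geometry: %d frames over [%.1f, %.1f] deg\n",
              length(x$angles), min(x$angles), max(x$angles)))
  cat(sprintf("  SAD %.0f mm, SDD %.0f mm, detector %dx%d px @ %.2fx%.2f mm",
              x$sad, x$sdd, x$n_u, x$n_v, x$du, x$dv))
  if (x$detector_offset_u != 0)
    cat(sprintf(" (half-fan, offset %.1f mm)", x$detector_offset_u))
  cat("\n")
  invisible(x)
}

#' 3D attenuation volume on a regular grid
#'
#' A scalar attenuation field (mm^-1) with voxel spacing and world origin
#' (coordinates of the center of voxel `[1,1,1]`, in mm). Axis convention:
#' x = left-right, y = anterior-posterior, z = superior-inferior.
#'
#' @param data 3D numeric array of attenuation values (mm^-1).
#' @param spacing Voxel spacing, length-3 (mm).
#' @param origin World coordinates of the first voxel center (mm). Default
#'   centers the grid on the isocenter.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(data, spacing, origin = NULL) {
  if (length(dim(data)) != 3L) stop("'data' must be a 3D array")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("'spacing' must be positive")
  if (!all(is.finite(data))) stop("'data' must be finite")
  if (is.null(origin)) origin <- -(dim(data) - 1) / 2 * spacing
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Volume grid %dx%dx%d @ %.3gx%.3gx%.3g mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$data), max(x$data)))
  invisible(x)
}

# grid metadata helpers used throughout the C++ interface
grid_dims    <- function(v) as.integer(dim(v$data))
grid_spacing <- function(v) as.numeric(v$spacing)
grid_origin  <- function(v) as.numeric(v$origin)

#' Grid definition without data
#'
#' A dims/spacing/origin triple describing a volume grid; accepted wherever a
#' target grid is needed without voxel data (e.g. [fdk_reconstruct()],
#' [motion_basis()], [render_volume()]). The default origin centers the grid
#' on the isocenter.
#'
#' @param dims Voxel counts, length 3.
#' @param spacing Voxel size (mm), length 3 (recycled).
#' @param origin World coordinates of the first voxel center (mm).
#' @return A list with elements `dims`, `spacing`, `origin`.
#' @export
grid_def <- function(dims, spacing, origin = NULL) {
  dims <- as.integer(dims)
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (is.null(origin)) origin <- -(dims - 1) / 2 * spacing
  list(dims = dims, spacing = spacing, origin = as.numeric(origin))
}

# coarsen a grid definition by an integer factor, preserving the center
coarsen_grid <- function(gd, factor = 2) {
  dims2 <- pmax(as.integer(ceiling(gd$dims / factor)), 1L)
  spacing2 <- gd$spacing * factor
  center <- gd$origin + (gd$dims - 1) / 2 * gd$spacing
  grid_def(dims2, spacing2, origin = center - (dims2 - 1) / 2 * spacing2)
}

# world-coordinate bounding box of voxel centers
grid_extent <- function(gd) {
  list(lo = gd$origin, hi = gd$origin + (gd$dims - 1) * gd$spacing)
}

#' Stack of cone-beam projection frames
#'
#' Post-log projections (line integrals, dimensionless) with their acquisition
#' geometry. Frame `i` was acquired at `geometry$angles[i]`.
#'
#' @param frames 3D array `(n_v, n_u, n_frames)` of post-log projections, or a
#'   single `(n_v, n_u)` matrix.
#' @param geometry A [scan_geometry()].
#' @return An object of class `projection_set`.
#' @export
projection_set <- function(frames, geometry) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  stopifnot(inherits(geometry, "scan_geometry"))
  d <- dim(frames)
  if (d[1] != geometry$n_v || d[2] != geometry$n_u)
    stop(sprintf("frame shape (%d, %d) does not match geometry (n_v=%d, n_u=%d)",
                 d[1], d[2], geometry$n_v, geometry$n_u))
  if (d[3] != length(geometry$angles))
    stop("number of frames does not match number of angles")
  if (!all(is.finite(frames))) stop("frames must be finite")
  structure(list(frames = frames, geometry = geometry,
                 acquisition_index = seq_len(d[3])),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Projection set: %d frames of %dx%d px, angles [%.1f, %.1f] deg\n",
              d[3], d[1], d[2], min(x$geometry$angles), max(x$geometry$angles)))
  invisible(x)
}

n_frames <- function(ps) dim(ps$frames)[3]

#' Read/write volumes as NIfTI
#'
#' Volumes are exchanged as NIfTI images with the grid spacing in the header;
#' the world origin is stored in the qform offset.
#'
#' @param volume A [volume_grid()].
#' @param path Output file (`.nii` or `.nii.gz`).
#' @return `write_volume` returns `path` invisibly; `read_volume` returns a
#'   [volume_grid()].
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$data, pixdim = volume$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  volume_grid(array(as.numeric(img), dim(img)[1:3]),
              spacing = RNifti::pixdim(img)[1:3])
}

#' Save or load a projection set
#'
#' The frames go to an RDS container next to a YAML sidecar mirroring the
#' `scan_geometry` fields, so the geometry stays human-readable.
#'
#' @param ps A [projection_set()].
#' @param path Output `.rds` path; the geometry is written to
#'   `paste0(path, ".yaml")`.
#' @return `write_projection_set` returns `path` invisibly;
#'   `read_projection_set` returns a [projection_set()].
#' @export
write_projection_set <- function(ps, path) {
  saveRDS(ps, path)
  geom <- ps$geometry
  yaml::write_yaml(list(sad = geom$sad, sdd = geom$sdd, n_u = geom$n_u,
                        n_v = geom$n_v, du = geom$du, dv = geom$dv,
                        detector_offset_u = geom$detector_offset_u,
                        frame_rate = geom$frame_rate,
                        n_frames = length(geom$angles)),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_projection_set
#' @export
read_projection_set <- function(path) {
  ps <- readRDS(path)
  stopifnot(inherits(ps, "projection_set"))
  ps
}
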