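#' Mean relative error between dynamic volume sequences
#'
#' Per frame, the L2 norm of the voxelwise difference divided by the L2 norm
#' of the ground truth; averaged over frames.
#'
#' @param est,truth Single [volume_grid()]s (or arrays), or lists of them.
#' @return Scalar mean relative error.
#' @export
relative_error <- function(est, truth) {
  le <- if (inherits(est, "volume_grid") || !is.list(est)) list(est) else est
  lt <- if (inherits(truth, "volume_grid") || !is.list(truth)) list(truth)
        else truth
  stopifnot(length(le) == length(lt))
  re <- mapply(function(a, b) {
    av <- if (inherits(a, "volume_grid")) a$data else a
    bv <- if (inherits(b, "volume_grid")) b$data else b
    sqrt(sum((av - bv)^2)) / sqrt(sum(bv^2))
  }, le, lt)
  mean(re)
}

#' Volumetric structural similarity (SSIM)
#'
#' Standard SSIM with a 3D Gaussian window (sigma 1.5, radius 5), constants
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` with the data range `L` taken from
#' the truth volume (shared between the two inputs, so the measure is
#' symmetric), averaged over the volume.
#'
#' @param est,truth [volume_grid()]s or arrays on the same grid.
#' @param sigma Gaussian window sigma (voxels).
#' @param data_range Optional fixed `L`; default `max(truth) - min(truth)`.
#' @return Scalar in (-1, 1].
#' @export
ssim_volume <- function(est, truth, sigma = 1.5, data_range = NULL) {
  a <- if (inherits(est, "volume_grid")) est$data else est
  b <- if (inherits(truth, "volume_grid")) truth$data else truth
  if (!all(dim(a) == dim(b))) stop("grid mismatch")
  if (is.null(data_range)) data_range <- diff(range(b))
  if (data_range <= 0) data_range <- 1
  d <- dim(a)
  r <- 5L
  blur <- function(v) array(cpp_gaussian_blur3(as.numeric(v), d, sigma, r), d)
  mu1 <- blur(a); mu2 <- blur(b)
  s11 <- blur(a * a) - mu1^2
  s22 <- blur(b * b) - mu2^2
  s12 <- blur(a * b) - mu1 * mu2
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  num <- (2 * mu1 * mu2 + c1) * (2 * s12 + c2)
  den <- (mu1^2 + mu2^2 + c1) * (s11 + s22 + c2)
  mean(num / den)
}

#' Tumor center-of-mass error
#'
#' Euclidean distance (mm) between the centroids of two binary masks in
#' world coordinates. An empty estimated mask yields `NA` with a warning (a
#' flagged error state, not a zero); callers exclude and count such frames.
#'
#' @param est,truth Binary [volume_grid()] masks.
#' @param spacing Unused when masks are `volume_grid`s (kept for arrays).
#' @return Distance in mm, or `NA` for an empty estimate.
#' @export
come <- function(est, truth, spacing = NULL) {
  if (!inherits(est, "volume_grid")) est <- volume_grid(est, spacing)
  if (!inherits(truth, "volume_grid")) truth <- volume_grid(truth, spacing)
  c1 <- mask_centroid(est)
  c2 <- mask_centroid(truth)
  if (anyNA(c1)) {
    warning("empty estimated mask; COME undefined for this frame")
    return(NA_real_)
  }
  sqrt(sum((c1 - c2)^2))
}

#' Dice similarity coefficient
#'
#' `2 |A and B| / (|A| + |B|)`; 1 for identical non-empty masks, 0 for
#' disjoint ones.
#'
#' @param est,truth Binary masks ([volume_grid()]s or arrays).
#' @return Scalar in `[0, 1]`.
#' @export
dsc <- function(est, truth) {
  a <- (if (inherits(est, "volume_grid")) est$data else est) != 0
  b <- (if (inherits(truth, "volume_grid")) truth$data else truth) != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Amsterdam-Shroud respiratory trace
#'
#' Builds the Amsterdam-Shroud image of a projection sequence — per frame,
#' the superior-inferior intensity gradient is integrated along the
#' horizontal detector axis over a region of interest, forming one column —
#' and extracts a breathing trace: per frame, the sub-pixel (parabolic-fit)
#' location of the strongest gradient-magnitude edge, in detector mm. A
#' per-row z-normalized copy of the shroud (contrast enhancement that
#' suppresses static edges) is returned alongside for display and
#' correlation work.
#'
#' @param projections A [projection_set()] (or plain `(n_v, n_u, Np)` array
#'   with `dv` supplied).
#' @param roi_u,roi_v Optional index ranges restricting the detector region
#'   of interest.
#' @param dv Detector row pitch, required for plain arrays.
#' @return List with `trace` (mm per frame), `shroud` (the AS image,
#'   `n_v x Np`), and `trace_px`.
#' @export
amsterdam_shroud <- function(projections, roi_u = NULL, roi_v = NULL,
                             dv = NULL) {
  if (inherits(projections, "projection_set")) {
    fr <- projections$frames
    dv <- projections$geometry$dv
  } else {
    fr <- projections
    if (is.null(dv)) stop("'dv' required for plain arrays")
  }
  nv <- dim(fr)[1]; np <- dim(fr)[3]
  if (is.null(roi_u)) roi_u <- seq_len(dim(fr)[2])
  if (is.null(roi_v)) roi_v <- seq_len(nv)
  # SI gradient per frame, integrated along u
  shroud <- matrix(0, nv, np)
  for (i in seq_len(np)) {
    f <- fr[, roi_u, i, drop = FALSE][, , 1]
    g <- rbind(diff(f), 0)
    shroud[, i] <- rowSums(g)
  }
  shroud <- shroud[roi_v, , drop = FALSE]
  # per-row z-normalization over time: enhanced copy for display
  mu <- rowMeans(shroud)
  sdv <- apply(shroud, 1, sd)
  sdv[sdv < 1e-12] <- 1
  enh <- (shroud - mu) / sdv
  score <- abs(shroud)
  trace_px <- numeric(np)
  for (i in seq_len(np)) {
    s <- score[, i]
    k <- which.max(s)
    if (k > 1 && k < length(s)) {
      den <- s[k - 1] - 2 * s[k] + s[k + 1]
      off <- if (abs(den) > 1e-12) 0.5 * (s[k - 1] - s[k + 1]) / den else 0
      trace_px[i] <- k + max(min(off, 0.5), -0.5)
    } else trace_px[i] <- k
  }
  list(trace = trace_px * dv, trace_px = trace_px, shroud = shroud,
       enhanced = enh)
}

#' Pearson correlation between motion traces
#'
#' Thin wrapper over [stats::cor()] kept for a uniform metric surface.
#'
#' @param trace_a,trace_b Numeric vectors of equal length.
#' @return Correlation in `[-1, 1]`.
#' @export
trace_correlation <- function(trace_a, trace_b) {
  stats::cor(trace_a, trace_b)
}
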