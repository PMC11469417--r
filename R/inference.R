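#' Propagate a binary contour with a displacement field
#'
#' Warps a binary mask at the displaced coordinates (pull-back, same
#' convention as [warp_volume()]) and returns a binary result. The default
#' samples the mask trilinearly and thresholds the result at 0.5 — the
#' half-level set moves smoothly with sub-voxel displacements, so tracked
#' centroids are not quantized to the voxel grid; `"nearest"` sampling is
#' available as the simpler alternative. Used for markerless tumor
#' tracking: the reference tumor contour is propagated to each time point
#' with the inferred real-time DVF.
#'
#' @param mask A [volume_grid()] with 0/1 data (or a logical array on the
#'   DVF's grid).
#' @param d A [dvf()] on the same grid.
#' @param method `"linear"` (trilinear + 0.5 threshold) or `"nearest"`.
#' @return A [volume_grid()] with 0/1 data.
#' @export
propagate_contour <- function(mask, d, method = c("linear", "nearest")) {
  method <- match.arg(method)
  m <- if (inherits(mask, "volume_grid")) mask$data else mask
  if (!all(dim(m) == d$dims)) stop("grid mismatch between mask and DVF")
  if (method == "nearest") {
    out <- cpp_warp_nearest(as.numeric(m != 0), dvf_flat(d), d$dims,
                            d$spacing, d$origin)
    out <- as.numeric(out != 0)
  } else {
    res <- cpp_warp_forward(as.numeric(m != 0), dvf_flat(d), d$dims,
                            d$spacing, d$origin)
    out <- as.numeric(res$data > 0.5)
  }
  volume_grid(array(out, d$dims), d$spacing, d$origin)
}

#' Segment the tumor from a reconstructed reference volume
#'
#' Thresholds the volume, applies a one-voxel morphological opening (which
#' severs partial-volume bridges between the tumor and the chest wall), and
#' returns the largest connected component other than the body envelope,
#' restored by dilation constrained to the thresholded mask. Intended for
#' spherical-tumor phantoms where the tumor is the only
#' soft-tissue-density object detached from the body.
#'
#' @param volume A [volume_grid()].
#' @param threshold Attenuation threshold (mm^-1); defaults to the midpoint
#'   of the volume's range.
#' @param min_size Smallest plausible component (voxels); smaller blobs are
#'   treated as noise.
#' @return A [volume_grid()] binary mask (all zero if nothing qualifies).
#' @export
segment_tumor <- function(volume, threshold = NULL, min_size = 27) {
  v <- volume$data
  if (is.null(threshold)) threshold <- mean(range(v))
  thr_mask <- v > threshold
  core <- cpp_erode6(as.logical(thr_mask), dim(v), 1L)
  labs <- cpp_label_components(core, dim(v))
  sizes <- tabulate(labs)
  mask <- array(0, dim(v))
  if (length(sizes) >= 2) {
    ord <- order(sizes, decreasing = TRUE)
    cand <- ord[-1]
    cand <- cand[sizes[cand] >= min_size]
    if (length(cand) > 0) {
      sel <- labs == cand[1]
      sel <- cpp_dilate6(sel, dim(v), 2L, as.logical(thr_mask))
      mask[sel] <- 1
    }
  }
  volume_grid(mask, volume$spacing, volume$origin)
}

#' Mask centroid in world coordinates
#'
#' @param mask A [volume_grid()] binary mask.
#' @return Length-3 centroid (mm), or `NA`s for an empty mask.
#' @export
mask_centroid <- function(mask) {
  m <- mask$data
  idx <- which(m != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(c(NA_real_, NA_real_, NA_real_))
  colMeans((idx - 1) %*% diag(mask$spacing)) + mask$origin
}
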