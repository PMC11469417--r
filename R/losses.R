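#' Training loss weights
#'
#' The weighting factors applied to each objective in the staged training
#' schedule. Defaults follow the reference configuration: image similarity 1,
#' projection similarity 1, total variation 2e-4, basis ortho-normality 1,
#' zero-mean score 1e-3, DVF self-consistency 1e3, augmentation 1e-4.
#' Zeroing a single weight reproduces the corresponding ablation variant.
#'
#' @param image,projection,tv,mbc,zero_mean,self_consistency,augmentation
#'   Non-negative weights.
#' @return Named numeric vector of class `loss_weights`.
#' @export
loss_weights <- function(image = 1, projection = 1, tv = 2e-4, mbc = 1,
                         zero_mean = 1e-3, self_consistency = 1e3,
                         augmentation = 1e-4) {
  w <- c(image = image, projection = projection, tv = tv, mbc = mbc,
         zero_mean = zero_mean, self_consistency = self_consistency,
         augmentation = augmentation)
  if (any(w < 0) || any(!is.finite(w))) stop("loss weights must be >= 0")
  structure(w, class = "loss_weights")
}

#' Image-domain similarity loss
#'
#' Mean squared voxel error between the rendered reference volume and a label
#' volume (the FDK warm-start at low resolution, the upsampled low-resolution
#' solution at high resolution).
#'
#' @param rendered,label [volume_grid()]s (or plain arrays) on the same grid.
#' @return Scalar loss.
#' @export
loss_image_similarity <- function(rendered, label) {
  a <- if (inherits(rendered, "volume_grid")) rendered$data else rendered
  b <- if (inherits(label, "volume_grid")) label$data else label
  if (!all(dim(a) == dim(b))) stop("grid mismatch")
  mean((a - b)^2)
}

#' Projection-domain similarity loss
#'
#' Mean squared pixel error between a batch of DRRs and the corresponding
#' measured projections, averaged over batch and pixels.
#'
#' @param drrs,measured Arrays `(n_v, n_u, n_batch)` (or matrices for a
#'   single frame).
#' @return Scalar loss.
#' @export
loss_projection_similarity <- function(drrs, measured) {
  if (!all(dim(drrs) == dim(measured))) stop("shape mismatch")
  mean((drrs - measured)^2)
}

#' Isotropic total-variation loss
#'
#' Mean over voxels of the forward-difference gradient magnitude
#' `|grad I| = sqrt(dx^2 + dy^2 + dz^2)`; differences across the far face are
#' zero. Suppresses high-frequency noise while preserving anatomy edges.
#'
#' @param volume A [volume_grid()] or 3D array.
#' @return Scalar loss.
#' @export
loss_tv <- function(volume) {
  v <- if (inherits(volume, "volume_grid")) volume$data else volume
  mean(sqrt(tv_diff2(v)$g2))
}

# squared forward-difference gradient magnitude (zero beyond the far face)
tv_diff2 <- function(v) {
  d <- dim(v)
  dx <- array(0, d); dy <- array(0, d); dz <- array(0, d)
  if (d[1] > 1) dx[-d[1], , ] <- v[-1, , ] - v[-d[1], , ]
  if (d[2] > 1) dy[, -d[2], ] <- v[, -1, ] - v[, -d[2], ]
  if (d[3] > 1) dz[, , -d[3]] <- v[, , -1] - v[, , -d[3]]
  list(dx = dx, dy = dy, dz = dz, g2 = dx^2 + dy^2 + dz^2)
}

# gradient of loss_tv w.r.t. the voxel values (smoothed at |grad| ~ 0)
tv_gradient <- function(v, eps = 1e-8) {
  d <- dim(v)
  t <- tv_diff2(v)
  mag <- sqrt(t$g2 + eps^2)
  gx <- t$dx / mag; gy <- t$dy / mag; gz <- t$dz / mag
  g <- array(0, d)
  g[-1, , ] <- g[-1, , ] + gx[-d[1], , ]
  g[-d[1], , ] <- g[-d[1], , ] - gx[-d[1], , ]
  g[, -1, ] <- g[, -1, ] + gy[, -d[2], ]
  g[, -d[2], ] <- g[, -d[2], ] - gy[, -d[2], ]
  g[, , -1] <- g[, , -1] + gz[, , -d[3]]
  g[, , -d[3]] <- g[, , -d[3]] - gz[, , -d[3]]
  g / length(v)
}

#' Motion-basis ortho-normality loss
#'
#' Promotes an ortho-normal basis: for each Cartesian direction `k`,
#' `(||e_{i,k}||^2 - 1)^2` for every level plus the squared pairwise inner
#' products between levels, averaged over the nine components. Norms and
#' inner products use the voxel-mean discretization
#' `<a,b> = mean(a * b)` over the dense evaluated fields, so a unit-norm
#' component has RMS amplitude 1 and the scores carry the mm scale.
#'
#' @param basis A [motion_basis()] (evaluated on `grid`) or a pre-evaluated
#'   `(n_voxels, 9)` field matrix.
#' @param grid Required when `basis` is a [motion_basis()].
#' @return Scalar loss.
#' @export
loss_mbc_orthonormality <- function(basis, grid = NULL) {
  E <- if (is.matrix(basis)) basis else evaluate_basis(basis, grid)
  G <- crossprod(E) / nrow(E)
  loss <- 0
  for (k in 1:3) {
    j <- score_index(1:3, k)
    for (a in 1:3) {
      loss <- loss + (G[j[a], j[a]] - 1)^2
      if (a < 3) for (b in (a + 1):3) loss <- loss + G[j[a], j[b]]^2
    }
  }
  loss / 9
}

# gradient of loss_mbc_orthonormality w.r.t. the dense fields E, written as
# one matrix product E %*% C with a 9x9 coefficient matrix
mbc_gradient <- function(E) {
  n <- nrow(E)
  G <- crossprod(E) / n
  C <- matrix(0, 9, 9)
  for (k in 1:3) {
    j <- score_index(1:3, k)
    for (a in 1:3) {
      C[j[a], j[a]] <- C[j[a], j[a]] + 4 * (G[j[a], j[a]] - 1)
      if (a < 3) for (b in (a + 1):3) {
        C[j[b], j[a]] <- C[j[b], j[a]] + 2 * G[j[a], j[b]]
        C[j[a], j[b]] <- C[j[a], j[b]] + 2 * G[j[a], j[b]]
      }
    }
  }
  (E %*% C) / (9 * n)
}

#' Zero-mean score loss
#'
#' Penalizes the squared per-channel mean of the motion-basis scores over the
#' batch (an unbiased streaming estimate of the mean over all projections),
#' removing the constant baseline that the reference volume should absorb.
#'
#' @param scores Matrix `(9, n_batch)`.
#' @return Scalar loss.
#' @export
loss_zero_mean <- function(scores) {
  stopifnot(nrow(scores) == 9)
  mean(rowMeans(scores)^2)
}

zero_mean_gradient <- function(scores) {
  B <- ncol(scores)
  matrix(rep(2 * rowMeans(scores) / (9 * B), B), 9, B)
}

#' DVF self-consistency loss
#'
#' Warping the reference volume forward by `d` and back by the iterative
#' inverse of `d` must return the reference volume. The mean squared error is
#' taken over voxels whose round-trip sampling stayed inside the field of
#' view (border clamping is not a motion error).
#'
#' @param ref Reference [volume_grid()].
#' @param d A [dvf()] (or list of them, averaged as a batch).
#' @param iterations Inversion iterations (default 3).
#' @return Scalar loss.
#' @export
loss_self_consistency <- function(ref, d, iterations = 3) {
  ds <- if (inherits(d, "dvf")) list(d) else d
  total <- 0
  for (di in ds) {
    fwd <- warp_volume(ref, di)
    dinv <- invert_dvf(di, iterations)
    back <- warp_volume(fwd, dinv)
    mask <- attr(fwd, "inside") & attr(back, "inside")
    total <- total + if (any(mask))
      mean((back$data[mask] - ref$data[mask])^2) else 0
  }
  total / length(ds)
}

#' Motion augmentation configuration
#'
#' Random rescaling of solved motion-basis scores used to synthesize unseen
#' motion states: `w'[i,k] = r1 * r2[i,k] * w[i,k]` with one overall draw
#' `r1 ~ U(0.6, 2.0)` per projection instance (keeping the scores of an
#' instance correlated) and independent `r2[i,k] ~ U(0.8, 1.2)` per channel.
#'
#' @param r1_range,r2_range Uniform sampling ranges.
#' @param mode One of `"off"`, `"angle_only"`, `"motion_and_angle"`.
#' @return Object of class `augmentation_config`.
#' @export
augmentation_config <- function(r1_range = c(0.6, 2.0),
                                r2_range = c(0.8, 1.2),
                                mode = c("off", "angle_only",
                                         "motion_and_angle")) {
  mode <- match.arg(mode)
  structure(list(r1_range = r1_range, r2_range = r2_range, mode = mode),
            class = "augmentation_config")
}

#' Randomly rescale motion-basis scores
#'
#' @param scores Matrix `(9, n_batch)` (or length-9 vector).
#' @param cfg An [augmentation_config()].
#' @return Rescaled scores, same shape.
#' @export
augment_scores <- function(scores, cfg = augmentation_config()) {
  vec <- is.null(dim(scores))
  if (vec) scores <- matrix(scores, 9, 1)
  B <- ncol(scores)
  r1 <- runif(B, cfg$r1_range[1], cfg$r1_range[2])
  r2 <- matrix(runif(9 * B, cfg$r2_range[1], cfg$r2_range[2]), 9, B)
  out <- sweep(scores * r2, 2, r1, `*`)
  if (vec) out[, 1] else out
}

#' Augmentation (score-consistency) loss
#'
#' Mean squared difference between the encoder's scores on augmented DRRs and
#' the augmented target scores, averaged over the nine channels and the
#' batch.
#'
#' @param predicted,target Matrices `(9, n_batch)`.
#' @return Scalar loss.
#' @export
loss_augmentation <- function(predicted, target) {
  if (!all(dim(predicted) == dim(target))) stop("shape mismatch")
  mean((predicted - target)^2)
}
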