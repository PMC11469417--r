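#' Multi-level B-spline motion basis
#'
#' The low-rank motion model represents each displacement field as a linear
#' combination of nine spatial motion basis components (MBCs)
#' `e_{i,k}(x)`: three hierarchical levels `i` times three Cartesian
#' directions `k`. Each component is a cubic B-spline interpolant of a
#' learnable control-point grid; the control-point count per axis doubles at
#' each higher level so that level 1 carries the coarse bulk motion and level
#' 3 the fine detail.
#'
#' Component ordering used throughout the package (scores, basis fields):
#' `(i=1,x), (i=1,y), (i=1,z), (i=2,x), ..., (i=3,z)`.
#'
#' @param grid Grid definition (or [volume_grid()]) whose world extent the
#'   basis must cover.
#' @param base_control Control-point counts per axis at level 1 (doubled for
#'   each subsequent level). Cubic splines need at least 4 per axis.
#' @param n_levels Number of hierarchy levels (default 3).
#' @return Object of class `motion_basis`: per-level control dims, knot
#'   spacing, origin, and a flat coefficient vector (initially zero, in mm).
#' @export
motion_basis <- function(grid, base_control = c(6, 6, 4), n_levels = 3) {
  gd <- if (inherits(grid, "volume_grid"))
    grid_def(dim(grid$data), grid$spacing, grid$origin) else grid
  ext <- grid_extent(gd)
  levels <- vector("list", n_levels)
  for (i in seq_len(n_levels)) {
    nc <- as.integer(base_control * 2^(i - 1))
    if (any(nc < 4)) stop("cubic B-splines need >= 4 control points per axis")
    delta <- (ext$hi - ext$lo) / (nc - 3)
    levels[[i]] <- list(nc = nc, x0 = ext$lo, delta = delta)
  }
  npar <- sum(vapply(levels, function(l) prod(l$nc), numeric(1))) * 3
  structure(list(levels = levels, n_levels = n_levels,
                 coef = numeric(npar)), class = "motion_basis")
}

#' @export
print.motion_basis <- function(x, ...) {
  dims <- vapply(x$levels, function(l) paste(l$nc, collapse = "x"), "")
  cat(sprintf("Motion basis: %d levels (%s control points), %d coefficients\n",
              x$n_levels, paste(dims, collapse = ", "), length(x$coef)))
  invisible(x)
}

# layout of the flat coefficient vector: level-major, direction-minor:
# [l1 kx | l1 ky | l1 kz | l2 kx | ...]; returns a data.frame of slices
basis_layout <- function(basis) {
  sizes <- rep(vapply(basis$levels, function(l) prod(l$nc), numeric(1)),
               each = 3)
  ends <- cumsum(sizes)
  data.frame(level = rep(seq_len(basis$n_levels), each = 3),
             k = rep(1:3, basis$n_levels),
             from = c(1, head(ends, -1) + 1), to = ends)
}

# column index into the 9-component ordering for (level i, direction k)
score_index <- function(i, k) (i - 1) * 3 + k

#' Evaluate the motion basis on a volume grid
#'
#' Returns the nine dense scalar fields `e_{i,k}(x)` obtained by cubic
#' B-spline interpolation of the coefficient grids. Linear in the
#' coefficients; the adjoint used in training is exact.
#'
#' @param basis A [motion_basis()].
#' @param grid Grid definition or [volume_grid()]; must lie inside the spline
#'   support (it does by construction when `grid` matches the one the basis
#'   was built on).
#' @return Matrix `(n_voxels, 9)`, columns in the `(i,k)` order documented in
#'   [motion_basis()].
#' @export
evaluate_basis <- function(basis, grid) {
  gd <- if (inherits(grid, "volume_grid"))
    grid_def(dim(grid$data), grid$spacing, grid$origin) else grid
  ext <- grid_extent(gd)
  lay <- basis_layout(basis)
  out <- matrix(0, prod(gd$dims), 9)
  for (r in seq_len(nrow(lay))) {
    lev <- basis$levels[[lay$level[r]]]
    sup_lo <- lev$x0 - 1e-9
    sup_hi <- lev$x0 + (lev$nc - 3) * lev$delta + 1e-9
    if (any(ext$lo < sup_lo) || any(ext$hi > sup_hi))
      stop("grid extends outside the B-spline support")
    out[, score_index(lay$level[r], lay$k[r])] <-
      cpp_bspline_eval(basis$coef[lay$from[r]:lay$to[r]], lev$nc,
                       gd$dims, gd$spacing, gd$origin, lev$x0, lev$delta)
  }
  out
}

# adjoint: dense-field gradients (n_voxels x 9) -> flat coefficient gradient
basis_adjoint <- function(basis, grid, gfields) {
  gd <- if (inherits(grid, "volume_grid"))
    grid_def(dim(grid$data), grid$spacing, grid$origin) else grid
  lay <- basis_layout(basis)
  gcoef <- numeric(length(basis$coef))
  for (r in seq_len(nrow(lay))) {
    lev <- basis$levels[[lay$level[r]]]
    j <- score_index(lay$level[r], lay$k[r])
    gcoef[lay$from[r]:lay$to[r]] <-
      cpp_bspline_adjoint(gfields[, j], lev$nc, gd$dims, gd$spacing,
                          gd$origin, lev$x0, lev$delta)
  }
  gcoef
}

#' Dense displacement field
#'
#' A 3-component displacement field (mm) on a volume grid, under the pull-back
#' convention `I(x) = Iref(x + d(x))`.
#'
#' @param displacement Array `(nx, ny, nz, 3)` or matrix `(n_voxels, 3)` of
#'   displacements in mm (components ordered x, y, z).
#' @param grid Grid definition or [volume_grid()] the field lives on.
#' @return Object of class `dvf`.
#' @export
dvf <- function(displacement, grid) {
  gd <- if (inherits(grid, "volume_grid"))
    grid_def(dim(grid$data), grid$spacing, grid$origin) else grid
  if (is.matrix(displacement)) {
    stopifnot(nrow(displacement) == prod(gd$dims), ncol(displacement) == 3)
    displacement <- array(displacement, c(gd$dims, 3L))
  }
  stopifnot(all(dim(displacement) == c(gd$dims, 3L)))
  if (!all(is.finite(displacement))) stop("displacement must be finite")
  structure(list(displacement = displacement, dims = gd$dims,
                 spacing = gd$spacing, origin = gd$origin), class = "dvf")
}

#' @export
print.dvf <- function(x, ...) {
  mag <- sqrt(rowSums(matrix(x$displacement, ncol = 3)^2))
  cat(sprintf("DVF on %s grid: |d| mean %.2f mm, max %.2f mm\n",
              paste(x$dims, collapse = "x"), mean(mag), max(mag)))
  invisible(x)
}

dvf_flat <- function(d) d$displacement

#' Compose a displacement field from basis and scores
#'
#' `d_k(x) = sum_i w[i,k] * e_{i,k}(x)` — the score-weighted combination of
#' the motion basis components. Linear in the scores.
#'
#' @param scores Numeric vector of 9 motion-basis scores, `(i,k)` order.
#' @param basis A [motion_basis()], or a pre-evaluated basis field matrix from
#'   [evaluate_basis()] (then `grid` must still be given for the metadata).
#' @param grid Grid definition or [volume_grid()].
#' @return A [dvf()].
#' @export
compose_dvf <- function(scores, basis, grid) {
  if (length(scores) != 9 || !all(is.finite(scores)))
    stop("'scores' must be 9 finite values")
  E <- if (is.matrix(basis)) basis else evaluate_basis(basis, grid)
  gd <- if (inherits(grid, "volume_grid"))
    grid_def(dim(grid$data), grid$spacing, grid$origin) else grid
  disp <- matrix(0, nrow(E), 3)
  for (k in 1:3) {
    j <- score_index(1:3, k)
    disp[, k] <- E[, j, drop = FALSE] %*% scores[j]
  }
  dvf(disp, gd)
}

#' Warp a volume by a displacement field
#'
#' `out(x) = in(x + d(x))` with trilinear interpolation; samples beyond the
#' grid clamp to the border value. The result carries an `inside` attribute
#' marking voxels whose sample stayed inside the field of view (used to mask
#' border effects out of the self-consistency loss).
#'
#' @param volume A [volume_grid()].
#' @param d A [dvf()] on the same grid.
#' @return A [volume_grid()] with attribute `inside` (logical array).
#' @export
warp_volume <- function(volume, d) {
  stopifnot(inherits(volume, "volume_grid"), inherits(d, "dvf"))
  if (!all(dim(volume$data) == d$dims)) stop("grid mismatch between volume and DVF")
  res <- cpp_warp_forward(volume$data, dvf_flat(d),
                          grid_dims(volume), grid_spacing(volume),
                          grid_origin(volume))
  out <- volume_grid(array(res$data, dim(volume$data)), volume$spacing,
                     volume$origin)
  attr(out, "inside") <- array(res$inside, dim(volume$data))
  out
}

#' Iterative displacement-field inversion
#'
#' Fixed-point iteration `dinv[n+1](x) = -d(x + dinv[n](x))` starting from
#' zero. Three iterations suffice in the contractive regime of smooth
#' respiratory fields; divergence is reported through the `residual`
#' attribute (mean composition residual `|d(x + dinv(x)) + dinv(x)|` in mm),
#' never as an error.
#'
#' @param d A [dvf()].
#' @param iterations Number of fixed-point iterations (default 3).
#' @return A [dvf()] with attribute `residual` (mean mm).
#' @export
invert_dvf <- function(d, iterations = 3) {
  stopifnot(inherits(d, "dvf"))
  out <- invert_raw(d, iterations)
  res <- cpp_inversion_residual(dvf_flat(d), dvf_flat(out), d$dims,
                                d$spacing, d$origin)
  attr(out, "residual") <- mean(res)
  out
}

# validation-free constructors and composition for the training hot path
dvf_fast <- function(disp, gd) {
  dim(disp) <- c(gd$dims, 3L)
  structure(list(displacement = disp, dims = gd$dims, spacing = gd$spacing,
                 origin = gd$origin), class = "dvf")
}

compose_fast <- function(scores, E, gd) {
  M <- matrix(0, 9, 3)
  for (k in 1:3) M[score_index(1:3, k), k] <- scores[score_index(1:3, k)]
  dvf_fast(E %*% M, gd)
}

# inversion without the residual diagnostic (training hot path)
invert_raw <- function(d, iterations = 3) {
  inv <- cpp_invert_dvf(dvf_flat(d), d$dims, d$spacing, d$origin,
                        as.integer(iterations))
  structure(list(displacement = array(inv, c(d$dims, 3L)), dims = d$dims,
                 spacing = d$spacing, origin = d$origin), class = "dvf")
}

#' Composition residual of an approximate inverse
#'
#' Per-voxel Euclidean norm of `d(x + dinv(x)) + dinv(x)` in mm.
#'
#' @param d,dinv Forward and (approximate) inverse [dvf()]s.
#' @return Numeric array of residual magnitudes.
#' @export
inversion_residual <- function(d, dinv) {
  array(cpp_inversion_residual(dvf_flat(d), dvf_flat(dinv), d$dims,
                               d$spacing, d$origin), d$dims)
}

#' Export a displacement field as 3-component NIfTI
#'
#' @param d A [dvf()].
#' @param path Output `.nii`/`.nii.gz` path.
#' @export
write_dvf <- function(d, path) {
  img <- RNifti::asNifti(d$displacement, pixdim = d$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}
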