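#' Hash-encoded implicit neural representation of the reference volume
#'
#' The static reference anatomy is represented continuously by a coordinate
#' network: a multiresolution learnable hash encoding (trilinearly
#' interpolated feature grids, dense where the grid fits the table and hashed
#' beyond) followed by a small ReLU MLP with a softplus output that keeps
#' attenuation non-negative. Levels grow geometrically from `base_resolution`
#' by `growth`.
#'
#' @param grid Grid definition or [volume_grid()]; the coordinate
#'   normalization bounds are the grid's world bounding box plus `margin`.
#' @param n_levels Number of encoding levels.
#' @param n_features Features per level.
#' @param table_log2 log2 of the hash-table size per level.
#' @param base_resolution Coarsest grid resolution (cells per axis).
#' @param growth Per-level geometric resolution growth.
#' @param hidden Hidden-layer widths of the MLP head.
#' @param margin Bounds margin as a fraction of the extent.
#' @param init_scale Uniform init range for the hash features.
#' @return Object of class `spatial_inr` holding the config and a flat
#'   parameter vector (tables first, then per MLP layer the weight matrix in
#'   column-major order followed by the biases).
#' @export
spatial_inr <- function(grid, n_levels = 12, n_features = 2, table_log2 = 19,
                        base_resolution = 8, growth = 1.38,
                        hidden = c(64, 64), margin = 0.05,
                        init_scale = 1e-4) {
  gd <- if (inherits(grid, "volume_grid"))
    grid_def(dim(grid$data), grid$spacing, grid$origin) else grid
  ext <- grid_extent(gd)
  pad <- margin * (ext$hi - ext$lo)
  cfg <- list(n_levels = as.integer(n_levels),
              n_features = as.integer(n_features),
              table_size = as.integer(2^table_log2),
              resolutions = as.integer(floor(base_resolution *
                                             growth^(seq_len(n_levels) - 1))),
              bounds_min = ext$lo - pad, bounds_max = ext$hi + pad,
              hidden = as.integer(hidden))
  n_tab <- n_levels * cfg$table_size * n_features
  ldims <- c(n_levels * n_features, hidden, 1L)
  n_mlp <- sum(ldims[-length(ldims)] * ldims[-1] + ldims[-1])
  params <- numeric(n_tab + n_mlp)
  params[seq_len(n_tab)] <- runif(n_tab, -init_scale, init_scale)
  off <- n_tab
  for (l in seq_len(length(ldims) - 1)) {
    ni <- ldims[l]; no <- ldims[l + 1]
    params[off + seq_len(ni * no)] <- rnorm(ni * no, sd = sqrt(2 / ni))
    off <- off + ni * no
    # biases zero, except the output bias: softplus(-4) ~ 0.018 mm^-1, a
    # soft-tissue-scale starting attenuation
    params[off + seq_len(no)] <- if (l == length(ldims) - 1) -4 else 0
    off <- off + no
  }
  structure(list(cfg = cfg, params = params, n_table = n_tab,
                 ldims = ldims), class = "spatial_inr")
}

#' @export
print.spatial_inr <- function(x, ...) {
  cat(sprintf(paste0("Spatial INR: %d hash levels (res %d..%d, table 2^%.0f),",
                     " MLP %s, %d parameters\n"),
              x$cfg$n_levels, min(x$cfg$resolutions), max(x$cfg$resolutions),
              log2(x$cfg$table_size),
              paste(x$cfg$hidden, collapse = "x"), length(x$params)))
  invisible(x)
}

# slice the flat parameter vector into table block and MLP weight matrices
inr_unpack <- function(inr) {
  ld <- inr$ldims
  nl <- length(ld) - 1L
  W <- vector("list", nl); b <- vector("list", nl)
  off <- inr$n_table
  for (l in seq_len(nl)) {
    ni <- ld[l]; no <- ld[l + 1]
    W[[l]] <- matrix(inr$params[off + seq_len(ni * no)], ni, no)
    off <- off + ni * no
    b[[l]] <- inr$params[off + seq_len(no)]
    off <- off + no
  }
  list(W = W, b = b)
}

softplus <- function(z) ifelse(z > 30, z, log1p(exp(z)))

# forward pass; returns list(values, cache) where cache holds the feature
# matrix and intermediate activations for the backward pass
inr_forward <- function(inr, gd, idx = NULL) {
  ii <- if (is.null(idx)) integer(0) else as.integer(idx - 1L)
  Fm <- cpp_inr_features(inr$params[seq_len(inr$n_table)], inr$cfg,
                         gd$dims, gd$spacing, gd$origin, ii)
  mp <- inr_unpack(inr)
  nl <- length(mp$W)
  acts <- vector("list", nl + 1)
  acts[[1]] <- Fm
  A <- Fm
  for (l in seq_len(nl - 1)) {
    Z <- A %*% mp$W[[l]]
    cpp_addbias_relu(Z, mp$b[[l]])     # in place: Z <- relu(Z + b)
    A <- Z
    acts[[l + 1]] <- A
  }
  zout <- as.numeric(A %*% mp$W[[nl]]) + mp$b[[nl]]
  list(values = cpp_softplus(zout), cache = list(acts = acts, zout = zout,
                                                 mp = mp, idx = idx))
}

# backward pass: dL/dvalues -> flat parameter gradient; reuses the forward
# cache when supplied
inr_grad <- function(inr, gd, gvals, idx = NULL, cache = NULL) {
  if (is.null(cache)) cache <- inr_forward(inr, gd, idx)$cache
  mp <- cache$mp
  nl <- length(mp$W)
  acts <- cache$acts
  gz <- cpp_mul_sigmoid(gvals, cache$zout)      # softplus'
  gparams <- numeric(length(inr$params))
  gW <- vector("list", nl); gb <- vector("list", nl)
  gW[[nl]] <- crossprod(acts[[nl]], gz)
  gb[[nl]] <- sum(gz)
  gA <- matrix(gz, ncol = 1) %*% t(mp$W[[nl]])  # n x h outer product
  for (l in rev(seq_len(nl - 1))) {
    cpp_relu_gate(gA, acts[[l + 1]])            # in place: gZ
    gZ <- gA
    gW[[l]] <- crossprod(acts[[l]], gZ)
    gb[[l]] <- colSums(gZ)
    gA <- gZ %*% t(mp$W[[l]])
  }
  ii <- if (is.null(idx)) integer(0) else as.integer(idx - 1L)
  gtab <- cpp_inr_feature_adjoint(gA, inr$params[seq_len(inr$n_table)],
                                  inr$cfg, gd$dims, gd$spacing, gd$origin,
                                  ii)
  gparams[seq_len(inr$n_table)] <- gtab
  off <- inr$n_table
  ld <- inr$ldims
  for (l in seq_len(nl)) {
    ni <- ld[l]; no <- ld[l + 1]
    gparams[off + seq_len(ni * no)] <- as.numeric(gW[[l]])
    off <- off + ni * no
    gparams[off + seq_len(no)] <- gb[[l]]
    off <- off + no
  }
  gparams
}

#' Render the reference volume from the coordinate network
#'
#' Queries the network at every voxel center of `grid` (or at a subset of
#' voxel indices). Deterministic given fixed parameters.
#'
#' @param inr A [spatial_inr()].
#' @param grid Grid definition or [volume_grid()]; must lie inside the
#'   normalization bounds.
#' @param idx Optional 1-based linear voxel indices to evaluate (default: all).
#' @return A [volume_grid()] (or a plain vector when `idx` is given).
#' @export
render_volume <- function(inr, grid, idx = NULL) {
  gd <- if (inherits(grid, "volume_grid"))
    grid_def(dim(grid$data), grid$spacing, grid$origin) else grid
  ext <- grid_extent(gd)
  if (any(ext$lo < inr$cfg$bounds_min - 1e-9) ||
      any(ext$hi > inr$cfg$bounds_max + 1e-9))
    stop("grid lies outside the network's coordinate bounds")
  v <- inr_forward(inr, gd, idx)$values
  if (!is.null(idx)) return(as.numeric(v))
  volume_grid(array(v, gd$dims), gd$spacing, gd$origin)
}

# compatibility wrapper used by tests/training: dL/dvalues -> parameter grad
inr_backward <- function(inr, grid, gvals, idx = NULL, cache = NULL) {
  gd <- if (inherits(grid, "volume_grid"))
    grid_def(dim(grid$data), grid$spacing, grid$origin) else grid
  inr_grad(inr, gd, as.numeric(gvals), idx = idx, cache = cache)
}

#' Convolutional motion encoder
#'
#' Maps a single (preprocessed) x-ray projection to the nine motion-basis
#' scores: six 3x3 stride-2 convolution layers with 2, 4, 8, 16, 32, 32
#' channels, each followed by batch normalization and ReLU, then a flatten
#' and one linear layer with nine outputs. Input frames are resampled to a
#' fixed `input_h x input_w` size and scaled to `[0, 1]` by a per-scan
#' intensity constant, which makes the input contract independent of detector
#' geometry and gantry angle.
#'
#' @param input_h,input_w Fixed input size (rows = detector v, cols = u).
#' @param channels Output channels of the six convolution layers.
#' @return Object of class `motion_encoder` with flat parameters, running
#'   batch-norm statistics, and the intensity scale (set at training time).
#' @export
motion_encoder <- function(input_h = 96, input_w = 128,
                           channels = c(2, 4, 8, 16, 32, 32)) {
  cfg <- list(channels = as.integer(channels), input_h = as.integer(input_h),
              input_w = as.integer(input_w))
  np <- cpp_cnn_nparam(cfg)
  ns <- cpp_cnn_nstat(cfg)
  params <- numeric(np)
  # He init per conv layer; BN gamma 1, beta 0; final linear small
  off <- 0
  ci <- 1
  for (co in cfg$channels) {
    nw <- co * ci * 9
    params[off + seq_len(nw)] <- rnorm(nw, sd = sqrt(2 / (ci * 9)))
    off <- off + nw + co                # conv bias stays 0
    params[off + seq_len(co)] <- 1      # gamma
    off <- off + 2 * co                 # gamma + beta
    ci <- co
  }
  nflat <- (np - off - 9) / 9
  params[off + seq_len(9 * nflat)] <- rnorm(9 * nflat, sd = 0.01)
  rstats <- numeric(ns)
  # running variance starts at 1
  soff <- 0
  for (co in cfg$channels) {
    rstats[soff + co + seq_len(co)] <- 1
    soff <- soff + 2 * co
  }
  message(sprintf("motion encoder: %d parameters", np))
  structure(list(cfg = cfg, params = params, rstats = rstats,
                 intensity_scale = NA_real_), class = "motion_encoder")
}

#' @export
print.motion_encoder <- function(x, ...) {
  cat(sprintf("Motion encoder CNN: %s channels, input %dx%d, %d parameters\n",
              paste(x$cfg$channels, collapse = "-"), x$cfg$input_h,
              x$cfg$input_w, length(x$params)))
  invisible(x)
}

# Resample frames to the fixed encoder input size and scale intensities;
# frames: matrix or (n_v, n_u, B) array. Returns flat array for the CNN.
preprocess_frames <- function(enc, frames) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  if (!all(is.finite(frames))) stop("NaN or Inf in input frame")
  B <- dim(frames)[3]
  H <- enc$cfg$input_h; W <- enc$cfg$input_w
  sc <- enc$intensity_scale
  if (!is.finite(sc) || sc <= 0) sc <- max(frames, 1e-12)
  out <- numeric(H * W * B)
  for (b in seq_len(B)) {
    r <- cpp_resize_bilinear(frames[, , b], H, W) / sc
    out[(b - 1) * H * W + seq_len(H * W)] <- r
  }
  out
}

# adjoint of preprocess_frames: gradient on CNN input -> per-frame gradient
preprocess_adjoint <- function(enc, ginput, nv, nu) {
  H <- enc$cfg$input_h; W <- enc$cfg$input_w
  B <- length(ginput) / (H * W)
  sc <- enc$intensity_scale
  g <- array(0, c(nv, nu, B))
  for (b in seq_len(B)) {
    gm <- matrix(ginput[(b - 1) * H * W + seq_len(H * W)], H, W)
    g[, , b] <- cpp_resize_bilinear_adjoint(gm, nv, nu) / sc
  }
  g
}

#' Estimate motion-basis scores from projections
#'
#' Runs the motion encoder on one or more frames. In eval mode (the default)
#' batch normalization uses the running statistics accumulated during
#' training, so the result for a frame does not depend on what it is batched
#' with.
#'
#' @param enc A [motion_encoder()].
#' @param frames Matrix `(n_v, n_u)` or array `(n_v, n_u, B)` of post-log
#'   projections.
#' @param train Use batch statistics and update running statistics.
#' @return Matrix `(9, B)` of scores (a length-9 vector for a single frame is
#'   returned as a 1-column matrix).
#' @export
encode_projection <- function(enc, frames, train = FALSE) {
  x <- preprocess_frames(enc, frames)
  B <- length(x) / (enc$cfg$input_h * enc$cfg$input_w)
  res <- cpp_cnn_forward(x, as.integer(B), enc$params, enc$rstats, enc$cfg,
                         train, 0.1, 1e-5)
  res$scores
}

# full forward with cache for training
encoder_forward <- function(enc, x, B, train) {
  cpp_cnn_forward(x, as.integer(B), enc$params, enc$rstats, enc$cfg,
                  train, 0.1, 1e-5)
}

encoder_backward <- function(enc, x, B, cache, gscores, train,
                             need_ginput = FALSE) {
  cpp_cnn_backward(x, as.integer(B), enc$params, cache, gscores, enc$cfg,
                   train, 1e-5, need_ginput)
}
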