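# Every objective is checked against a literal brute-force implementation
# written as explicit loops over the defining sums.

rel_diff <- function(a, b) abs(a - b) / max(abs(b), .Machine$double.xmin)

test_that("image similarity equals its elementwise definition", {
  set.seed(31)
  a <- array(rnorm(4 * 5 * 3), c(4, 5, 3))
  b <- array(rnorm(4 * 5 * 3), c(4, 5, 3))
  expect_identical(loss_image_similarity(a, a), 0)
  cdiff <- a + 0.7
  expect_equal(loss_image_similarity(cdiff, a), 0.49, tolerance = 1e-12)
  brute <- 0
  for (i in seq_along(a)) brute <- brute + (a[i] - b[i])^2
  expect_lt(rel_diff(loss_image_similarity(a, b), brute / length(a)), 1e-10)
  expect_error(loss_image_similarity(a, array(0, c(5, 4, 3))), "mismatch")
})

test_that("projection similarity matches the double-loop definition", {
  set.seed(32)
  drr <- array(rnorm(6 * 7 * 4), c(6, 7, 4))
  meas <- array(rnorm(6 * 7 * 4), c(6, 7, 4))
  expect_identical(loss_projection_similarity(drr, drr), 0)
  one <- drr; one[3, 4, 2] <- one[3, 4, 2] + 0.3
  expect_equal(loss_projection_similarity(one, drr), 0.09 / (4 * 42),
               tolerance = 1e-12)
  brute <- 0
  for (t in 1:4) for (i in 1:6) for (j in 1:7)
    brute <- brute + (drr[i, j, t] - meas[i, j, t])^2
  expect_lt(rel_diff(loss_projection_similarity(drr, meas),
                     brute / (4 * 42)), 1e-10)
})

test_that("total variation matches a hand count and a brute-force oracle", {
  expect_identical(loss_tv(array(3.3, c(4, 4, 4))), 0)
  # 1D step of height h along x in an 4x3x3 volume: one face of 3x3 voxels
  v <- array(0, c(4, 3, 3)); v[3:4, , ] <- 2
  expect_equal(loss_tv(v), 2 * 9 / 36, tolerance = 1e-12)
  set.seed(33)
  r <- array(rnorm(5 * 4 * 3), c(5, 4, 3))
  brute <- 0
  for (i in 1:5) for (j in 1:4) for (k in 1:3) {
    dx <- if (i < 5) r[i + 1, j, k] - r[i, j, k] else 0
    dy <- if (j < 4) r[i, j + 1, k] - r[i, j, k] else 0
    dz <- if (k < 3) r[i, j, k + 1] - r[i, j, k] else 0
    brute <- brute + sqrt(dx^2 + dy^2 + dz^2)
  }
  expect_lt(rel_diff(loss_tv(r), brute / 60), 1e-10)
  # the fused C++ path must agree with the R definition
  cppv <- rtcbct:::cpp_tv_loss_grad(r, dim(r), 1e-8, FALSE)$loss
  expect_lt(rel_diff(cppv, brute / 60), 1e-10)
})

test_that("basis ortho-normality loss matches the definition", {
  set.seed(34)
  n <- 200
  # orthonormal under the voxel-mean inner product -> loss 0
  q <- qr.Q(qr(matrix(rnorm(n * 9), n, 9))) * sqrt(n)
  expect_lt(loss_mbc_orthonormality(q), 1e-20)
  # a single component with squared norm 2: (2-1)^2/9 plus the zero-norm
  # penalty (0-1)^2 of each of the other eight components
  E1 <- matrix(0, n, 9); E1[, 1] <- sqrt(2)
  expect_equal(loss_mbc_orthonormality(E1), ((2 - 1)^2 + 8) / 9,
               tolerance = 1e-12)
  # random basis vs brute force over all norms and inner products
  E <- matrix(rnorm(n * 9), n, 9)
  brute <- 0
  for (k in 1:3) for (a in 1:3) {
    ja <- (a - 1) * 3 + k
    brute <- brute + (mean(E[, ja] * E[, ja]) - 1)^2
    if (a < 3) for (b in (a + 1):3) {
      jb <- (b - 1) * 3 + k
      brute <- brute + mean(E[, ja] * E[, jb])^2
    }
  }
  expect_lt(rel_diff(loss_mbc_orthonormality(E), brute / 9), 1e-10)
})

test_that("zero-mean score loss matches the definition", {
  set.seed(35)
  s <- matrix(rnorm(9 * 8), 9, 8)
  sym <- cbind(s, -s)
  expect_lt(loss_zero_mean(sym), 1e-30)
  expect_equal(loss_zero_mean(matrix(0.4, 9, 5)), 0.16, tolerance = 1e-12)
  brute <- 0
  for (j in 1:9) brute <- brute + mean(s[j, ])^2
  expect_lt(rel_diff(loss_zero_mean(s), brute / 9), 1e-10)
})

test_that("self-consistency loss: minimizers and step-by-step oracle", {
  set.seed(36)
  ref <- smooth_volume(c(14, 14, 14), c(3, 3, 3))
  gd <- grid_def(c(14, 14, 14), c(3, 3, 3))
  d0 <- dvf(array(0, c(14, 14, 14, 3)), gd)
  expect_identical(loss_self_consistency(ref, d0), 0)
  # constant translation: masked interior error is ~0
  dt <- array(0, c(14, 14, 14, 3)); dt[, , , 2] <- 6
  expect_lt(loss_self_consistency(ref, dvf(dt, gd)), 1e-20)
  # random smooth field vs explicit warp-invert-warp-MSE chain
  ds <- sinusoid_dvf(c(14, 14, 14), c(3, 3, 3), amplitude = 3, period = 80)
  fwd <- warp_volume(ref, ds)
  back <- warp_volume(fwd, invert_dvf(ds, 3))
  mask <- attr(fwd, "inside") & attr(back, "inside")
  brute <- mean((back$data[mask] - ref$data[mask])^2)
  expect_lt(rel_diff(loss_self_consistency(ref, ds), brute), 1e-10)
})

test_that("score augmentation stays in range and preserves zeros", {
  set.seed(37)
  cfg <- augmentation_config()
  w <- matrix(rnorm(9 * 50) + 2, 9, 50)
  degenerate <- augmentation_config(r1_range = c(1, 1), r2_range = c(1, 1))
  expect_equal(augment_scores(w, degenerate), w)
  expect_true(all(augment_scores(matrix(0, 9, 4), cfg) == 0))
  ratios <- replicate(200, augment_scores(w[, 1], cfg) / w[, 1])
  expect_true(all(ratios >= 0.48 - 1e-12 & ratios <= 2.4 + 1e-12))
  # one r1 per instance: per-column ratio spread bounded by the r2 range
  r <- augment_scores(w, cfg) / w
  spread <- apply(r, 2, max) / apply(r, 2, min)
  expect_true(all(spread <= 1.2 / 0.8 + 1e-9))
})

test_that("augmentation loss matches the channel/batch-normalized sum", {
  set.seed(38)
  p <- matrix(rnorm(9 * 6), 9, 6)
  q <- matrix(rnorm(9 * 6), 9, 6)
  expect_identical(loss_augmentation(p, p), 0)
  one <- p; one[5, 2] <- one[5, 2] + 0.3
  expect_equal(loss_augmentation(one, p), 0.09 / (9 * 6), tolerance = 1e-12)
  brute <- 0
  for (t in 1:6) for (j in 1:9) brute <- brute + (p[j, t] - q[j, t])^2
  expect_lt(rel_diff(loss_augmentation(p, q), brute / 54), 1e-10)
})

test_that("analytic loss gradients match finite differences", {
  set.seed(39)
  # TV
  v <- array(rnorm(6 * 5 * 4), c(6, 5, 4))
  g <- rtcbct:::tv_gradient(v)
  for (i in sample(length(v), 4)) {
    e <- 1e-7
    v1 <- v; v1[i] <- v1[i] + e
    v2 <- v; v2[i] <- v2[i] - e
    expect_equal(g[i], (loss_tv(v1) - loss_tv(v2)) / (2 * e),
                 tolerance = 1e-5)
  }
  gc <- array(rtcbct:::cpp_tv_loss_grad(v, dim(v), 1e-8, TRUE)$grad, dim(v))
  expect_equal(gc, g, tolerance = 1e-12)
  # basis ortho-normality
  E <- matrix(rnorm(50 * 9), 50, 9)
  gE <- rtcbct:::mbc_gradient(E)
  for (i in sample(length(E), 4)) {
    e <- 1e-7
    E1 <- E; E1[i] <- E1[i] + e
    E2 <- E; E2[i] <- E2[i] - e
    expect_equal(gE[i], (loss_mbc_orthonormality(E1) -
                           loss_mbc_orthonormality(E2)) / (2 * e),
                 tolerance = 1e-5)
  }
  # zero-mean
  s <- matrix(rnorm(27), 9, 3)
  gs <- rtcbct:::zero_mean_gradient(s)
  for (i in sample(27, 3)) {
    e <- 1e-7
    s1 <- s; s1[i] <- s1[i] + e
    s2 <- s; s2[i] <- s2[i] - e
    expect_equal(gs[i], (loss_zero_mean(s1) - loss_zero_mean(s2)) / (2 * e),
                 tolerance = 1e-6)
  }
})
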