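rel_diff <- function(a, b) abs(a - b) / max(abs(b), .Machine$double.xmin)

test_that("relative error matches its norm-ratio definition", {
  set.seed(61)
  a <- array(rnorm(5 * 5 * 5), c(5, 5, 5))
  b <- array(rnorm(5 * 5 * 5), c(5, 5, 5))
  expect_identical(relative_error(a, a), 0)
  expect_equal(relative_error(array(0, dim(b)), b), 1, tolerance = 1e-14)
  brute <- sqrt(sum((a - b)^2)) / sqrt(sum(b^2))
  expect_lt(rel_diff(relative_error(a, b), brute), 1e-10)
  # frame lists average per-frame ratios
  a2 <- array(rnorm(125), dim(a))
  expect_lt(rel_diff(relative_error(list(a, a2), list(b, b)),
                     (brute + sqrt(sum((a2 - b)^2)) / sqrt(sum(b^2))) / 2),
            1e-10)
})

test_that("volumetric SSIM: identity, symmetry, noise degradation", {
  set.seed(62)
  truth <- build_phantom(phantom_spec(c(32, 32, 16), c(4, 4, 4),
                                      tumor_diameter = 20))$volume
  expect_equal(ssim_volume(truth, truth), 1, tolerance = 1e-12)
  noisy <- truth
  noisy$data <- truth$data + rnorm(length(truth$data), 0,
                                   0.5 * diff(range(truth$data)))
  expect_lt(ssim_volume(noisy, truth), 0.5)
  dr <- diff(range(truth$data))
  expect_equal(ssim_volume(noisy, truth, data_range = dr),
               ssim_volume(truth, noisy, data_range = dr),
               tolerance = 1e-12)
  expect_lte(ssim_volume(noisy, truth), 1)
})

test_that("center-of-mass error: identity, known shift, empty estimate", {
  mask <- sphere_volume(c(20, 20, 20), c(2, 2, 2), radius = 10, value = 1)
  expect_identical(come(mask, mask), 0)
  shifted <- mask
  shifted$data <- mask$data * 0
  shifted$data[2:20, , ] <- mask$data[1:19, , ]   # one 2 mm voxel in +x
  expect_equal(come(shifted, mask), 2, tolerance = 1e-9)
  empty <- volume_grid(array(0, c(20, 20, 20)), c(2, 2, 2))
  expect_warning(v <- come(empty, mask), "empty")
  expect_true(is.na(v))
})

test_that("Dice coefficient matches the voxel-count definition", {
  m1 <- sphere_volume(c(24, 24, 24), c(2, 2, 2), radius = 12, value = 1)
  expect_identical(dsc(m1, m1), 1)
  disjoint <- m1
  disjoint$data <- 0 * m1$data
  disjoint$data[1:2, 1:2, 1:2] <- 1
  expect_identical(dsc(disjoint, m1), 0)
  # half-overlapping equal spheres vs explicit voxel counts
  sh <- m1
  sh$data <- 0 * m1$data
  sh$data[7:24, , ] <- m1$data[1:18, , ]
  inter <- sum(sh$data == 1 & m1$data == 1)
  expect_lt(rel_diff(dsc(sh, m1),
                     2 * inter / (sum(sh$data) + sum(m1$data))), 1e-12)
})

test_that("Amsterdam-Shroud traces recover breathing motion", {
  # synthetic projections with a bright horizontal edge whose position
  # oscillates sinusoidally: amplitude 6 px, 60 frames
  nv <- 48; nu <- 32; np <- 60
  amp <- 6
  pos <- 24 + amp * sin(2 * pi * (seq_len(np) - 1) / 20)
  frames <- array(0, c(nv, nu, np))
  for (i in seq_len(np)) {
    edge <- 1 / (1 + exp(-(seq_len(nv) - pos[i])))   # smooth step in v
    frames[, , i] <- outer(edge, rep(1, nu)) * 2
  }
  geom <- scan_geometry(1000, 1500, n_u = nu, n_v = nv, du = 2, dv = 2,
                        angles = (seq_len(np) - 1) * 6)
  as_res <- amsterdam_shroud(projection_set(frames, geom))
  expect_equal(dim(as_res$shroud), c(nv, np))
  rec_amp <- (max(as_res$trace_px) - min(as_res$trace_px)) / 2
  expect_lt(abs(rec_amp - amp), 1)
  expect_gt(abs(cor(as_res$trace_px, pos)), 0.99)

  # static scan: flat trace
  static <- array(frames[, , 1], c(nv, nu, np))
  tr0 <- amsterdam_shroud(static, dv = 2)$trace_px
  expect_lt(stats::var(tr0), 0.1)

  # identical sets: identical traces, unit correlation, zero error
  expect_identical(amsterdam_shroud(frames, dv = 2)$trace,
                   as_res$trace)
  expect_equal(trace_correlation(as_res$trace, as_res$trace), 1)
  expect_equal(mean(abs(as_res$trace - as_res$trace)), 0)
})

test_that("trace correlation equals the textbook formula", {
  set.seed(63)
  x <- rnorm(40); y <- rnorm(40)
  expect_equal(trace_correlation(x, x), 1)
  expect_equal(trace_correlation(x, -x), -1)
  brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_lt(rel_diff(trace_correlation(x, y), brute), 1e-10)
})
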