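test_that("basis evaluation: zeros, single-coefficient kernel, unity", {
  gd <- grid_def(c(24, 24, 24), c(4, 4, 4))
  b <- motion_basis(gd, c(6, 6, 6))
  E <- evaluate_basis(b, gd)
  expect_true(all(E == 0))

  # constant coefficients reproduce the constant (partition of unity)
  lay <- rtcbct:::basis_layout(b)
  b2 <- b
  b2$coef[lay$from[1]:lay$to[1]] <- 2.5
  E2 <- evaluate_basis(b2, gd)
  expect_equal(max(abs(E2[, 1] - 2.5)), 0, tolerance = 1e-12)
  expect_true(all(E2[, -1] == 0))

  # single unit coefficient: the field is the tensor-product cubic kernel;
  # at the control point itself the value is (2/3)^3
  b3 <- b
  lev <- b3$levels[[1]]
  cp <- c(3, 3, 3)   # interior control point (0-based)
  cp_lin <- cp[1] + lev$nc[1] * (cp[2] + lev$nc[2] * cp[3]) + 1
  b3$coef[lay$from[1] - 1 + cp_lin] <- 1
  # world position of that control point: x0 + (j - 1) * delta
  pos <- lev$x0 + (cp - 1) * lev$delta
  # closed-form uniform cubic B-spline (support |t| < 2 knots)
  bs3 <- function(t) {
    t <- abs(t)
    ifelse(t < 1, (4 - 6 * t^2 + 3 * t^3) / 6,
           ifelse(t < 2, (2 - t)^3 / 6, 0))
  }
  gd1 <- grid_def(c(5, 5, 5), c(4, 4, 4),
                  origin = pos - c(8, 8, 8))   # small patch around cp
  E3 <- evaluate_basis(b3, gd1)
  ax <- function(a) (gd1$origin[a] + (0:4) * 4 - pos[a]) / lev$delta[a]
  expected <- outer(outer(bs3(ax(1)), bs3(ax(2))), bs3(ax(3)))
  expect_equal(array(E3[, 1], c(5, 5, 5)), expected, tolerance = 1e-12)
  centre_val <- E3[cbind(which.min(abs(ax(1))) +
                           5 * (which.min(abs(ax(2))) - 1) +
                           25 * (which.min(abs(ax(3))) - 1)), 1]
  expect_equal(centre_val, (2 / 3)^3, tolerance = 1e-12)
})

test_that("control-point counts double per level and support is checked", {
  gd <- grid_def(c(16, 16, 16), c(4, 4, 4))
  b <- motion_basis(gd, c(6, 6, 4))
  expect_equal(b$levels[[2]]$nc, c(12L, 12L, 8L))
  expect_equal(b$levels[[3]]$nc, c(24L, 24L, 16L))
  big <- grid_def(c(16, 16, 16), c(8, 8, 8))   # twice the extent
  expect_error(evaluate_basis(b, big), "support")
})

test_that("DVF composition is linear in the scores", {
  set.seed(3)
  gd <- grid_def(c(12, 12, 12), c(4, 4, 4))
  b <- motion_basis(gd)
  b$coef <- rnorm(length(b$coef))
  E <- evaluate_basis(b, gd)
  w <- rnorm(9)
  expect_error(compose_dvf(c(w, 1), E, gd), "9")
  d0 <- compose_dvf(rep(0, 9), E, gd)
  expect_true(all(d0$displacement == 0))
  d1 <- compose_dvf(w, E, gd)
  d2 <- compose_dvf(2 * w, E, gd)
  expect_equal(d2$displacement, 2 * d1$displacement, tolerance = 1e-14)
  # single active channel reproduces that basis field in its direction
  dx <- compose_dvf(c(1, rep(0, 8)), E, gd)
  expect_equal(as.numeric(dx$displacement[, , , 1]), E[, 1])
  expect_true(all(dx$displacement[, , , 2:3] == 0))
})

test_that("warping: identity, integer shift, and inverse round trip", {
  set.seed(4)
  vol <- smooth_volume(c(16, 16, 16), c(2, 2, 2))
  gd <- grid_def(c(16, 16, 16), c(2, 2, 2))
  d0 <- dvf(array(0, c(16, 16, 16, 3)), gd)
  expect_identical(warp_volume(vol, d0)$data, vol$data)

  # +2 voxels along z: out(x) = in(x + 4 mm), interior bit-equal to a shift
  dt <- array(0, c(16, 16, 16, 3)); dt[, , , 3] <- 4
  wt <- warp_volume(vol, dvf(dt, gd))
  expect_identical(wt$data[, , 1:13], vol$data[, , 3:15])

  dsm <- sinusoid_dvf(c(16, 16, 16), c(2, 2, 2), amplitude = 2, period = 60)
  w1 <- warp_volume(vol, dsm)
  w2 <- warp_volume(w1, invert_dvf(dsm, 5))
  expect_lt(mean(abs(w2$data - vol$data)) / diff(range(vol$data)), 0.02)
  expect_error(warp_volume(vol, dvf(array(0, c(8, 8, 8, 3)),
                                    grid_def(c(8, 8, 8), c(2, 2, 2)))),
               "mismatch")
})

test_that("DVF inversion: exactness, residual bound, monotone convergence", {
  gd <- grid_def(c(12, 12, 12), c(4, 4, 4))
  d0 <- dvf(array(0, c(12, 12, 12, 3)), gd)
  expect_true(all(invert_dvf(d0)$displacement == 0))

  # constant translation: inverse is exactly -t after one iteration and
  # unchanged by further iterations
  dt <- array(0, c(12, 12, 12, 3)); dt[, , , 1] <- 3; dt[, , , 3] <- -5
  dcv <- dvf(dt, gd)
  i1 <- invert_dvf(dcv, 1)
  i3 <- invert_dvf(dcv, 3)
  expect_equal(i1$displacement, -dt, tolerance = 1e-14)
  expect_identical(i1$displacement, i3$displacement)

  # smooth sinusoid (5 mm / 100 mm): residual < 0.5 mm after 3 iterations,
  # decreasing monotonically over iterations 1..3
  ds <- sinusoid_dvf(c(24, 24, 24), c(4, 4, 4), amplitude = 5, period = 100)
  res <- sapply(1:3, function(it) attr(invert_dvf(ds, it), "residual"))
  expect_lt(res[3], 0.5)
  expect_true(all(diff(res) < 0))
})
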