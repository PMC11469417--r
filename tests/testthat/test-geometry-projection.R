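test_that("geometry and volume constructors validate their invariants", {
  expect_error(scan_geometry(1000, 900, 64, 64, 1, 1, angles = 0), "sdd")
  expect_error(scan_geometry(1000, 1500, 64, 64, 1, 1, angles = NaN),
               "angles")
  expect_error(volume_grid(array(NA_real_, c(2, 2, 2)), c(1, 1, 1)),
               "finite")
  expect_error(volume_grid(array(0, c(2, 2, 2)), c(1, 0, 1)), "positive")
  geom <- test_geometry(angles = c(0, 90))
  expect_error(projection_set(array(0, c(3, 3, 2)), geom), "frame shape")
  expect_error(projection_set(array(0, c(33, 33, 3)), geom), "number of")
})

test_that("forward projection of an all-zero volume is zero", {
  vol <- volume_grid(array(0, c(8, 8, 8)), c(2, 2, 2))
  p <- forward_project(vol, test_geometry(), 12.3)
  expect_true(all(p == 0))
})

test_that("central ray through a uniform unit cube integrates to its side", {
  # unit attenuation, 16 voxels at 2 mm: central path length L = 32 mm
  vol <- volume_grid(array(1, c(16, 16, 16)), c(2, 2, 2))
  geom <- test_geometry()
  pj <- forward_project(vol, geom, 0)
  ps <- siddon_project(vol, geom, 0)   # exact-path oracle
  expect_equal(ps[17, 17], 32, tolerance = 1e-12)
  expect_equal(pj[17, 17], 32, tolerance = 1e-6)
  expect_lt(max(abs(pj - ps)), 0.01 * max(ps))
})

test_that("projector matches a brute-force fine-step ray integrator", {
  set.seed(101)
  vol <- smooth_volume(c(16, 16, 16), c(2, 2, 2))
  vol$data <- abs(vol$data)
  geom <- test_geometry(n_u = 9, n_v = 9, du = 8, dv = 8)
  angle <- 37.7
  pj <- forward_project(vol, geom, angle)
  # independent dense-step integrator, written directly from the ray
  # geometry (step 0.05 mm, midpoint rule)
  brute <- matrix(0, 9, 9)
  a <- angle * pi / 180
  sdir <- c(-sin(a), cos(a), 0); uh <- c(cos(a), sin(a), 0); vh <- c(0, 0, 1)
  src <- 1000 * sdir
  for (iu in 1:9) for (iv in 1:9) {
    u <- (iu - 5) * 8; v <- (iv - 5) * 8
    pix <- src - 1500 * sdir + u * uh + v * vh
    dir <- (pix - src) / sqrt(sum((pix - src)^2))
    ts <- seq(960, 1040, by = 0.05)
    pos <- outer(ts, dir) + rep(src, each = length(ts))
    ci <- sweep(sweep(pos, 2, vol$origin), 2, vol$spacing, `/`)
    inside <- rowSums(ci > -0.5 & ci < 15.5) == 3
    cic <- pmin(pmax(ci, 0), 15)
    i0 <- pmin(floor(cic), 14)
    fr <- cic - i0
    acc <- numeric(length(ts))
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
        (if (dy) fr[, 2] else 1 - fr[, 2]) *
        (if (dz) fr[, 3] else 1 - fr[, 3])
      acc <- acc + w * vol$data[cbind(i0[, 1] + dx + 1, i0[, 2] + dy + 1,
                                      i0[, 3] + dz + 1)]
    }
    brute[iv, iu] <- sum(acc * inside) * 0.05
  }
  expect_lt(max(abs(pj - brute)), 0.01 * max(abs(brute)))
})

test_that("project_set matches per-angle projection and is 360-periodic", {
  set.seed(7)
  vol <- smooth_volume(c(12, 12, 12), c(3, 3, 3))
  vol$data <- abs(vol$data)
  geom <- test_geometry(angles = c(10, 130, 250), n_u = 17, n_v = 17,
                        du = 5, dv = 5)
  ps <- project_set(vol, geom)
  expect_equal(dim(ps$frames)[3], 3)
  for (i in 1:3)
    expect_identical(ps$frames[, , i],
                     forward_project(vol, geom, geom$angles[i]))
  expect_equal(forward_project(vol, geom, 10),
               forward_project(vol, geom, 370), tolerance = 1e-9)
})

test_that("projector adjoint identity holds on random instances", {
  set.seed(11)
  geom <- test_geometry(n_u = 21, n_v = 21, du = 5, dv = 5)
  for (angle in c(0, 33.3, 201.9)) {
    v <- array(rnorm(16^3), c(16, 16, 16))
    vg <- volume_grid(v, c(2, 2, 2))
    p <- matrix(rnorm(21 * 21), 21, 21)
    Av <- forward_project(vg, geom, angle)
    Atp <- backproject_gradient(p, vg, geom, angle)
    lhs <- sum(Av * p); rhs <- sum(v * Atp)
    expect_lt(abs(lhs - rhs), 1e-4 * abs(lhs))
  }
})

test_that("rotationally symmetric phantoms project identically at all angles", {
  # a binary sphere voxelized on a grid has only cubic symmetry; the
  # rotational-invariance property is tested on a smooth, compactly
  # supported radial bump (quintic smoothstep falloff)
  ax <- (0:47 - 23.5) * 2
  r <- sqrt(outer(outer(ax^2, ax^2, `+`), ax^2, `+`))
  s <- pmin(r / 40, 1)
  vol <- volume_grid(array(0.02 * (1 - (10 * s^3 - 15 * s^4 + 6 * s^5)),
                           c(48, 48, 48)), c(2, 2, 2))
  geom <- test_geometry(n_u = 25, n_v = 25, du = 6, dv = 6)
  f0 <- forward_project(vol, geom, 0)
  for (angle in c(45, 122.5, 270))
    expect_lt(max(abs(forward_project(vol, geom, angle) - f0)),
              1e-3 * max(f0))
})

test_that("FDK reconstructs a static uniform sphere", {
  vol <- sphere_volume(c(32, 32, 32), c(4, 4, 4), radius = 40)
  geom <- test_geometry(angles = (0:179) * 2, n_u = 64, n_v = 64,
                        du = 4, dv = 4)
  rec <- fdk_reconstruct(project_set(vol, geom), vol)
  gd <- grid_def(c(32, 32, 32), c(4, 4, 4))
  ax <- gd$origin[1] + (0:31) * 4
  inside <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`) <= 30^2
  expect_lt(abs(mean(rec$data[inside]) - 0.02), 0.1 * 0.02)
  expect_lt(relative_error(rec, vol), 0.2)
})

test_that("FDK error decreases monotonically with view count", {
  vol <- sphere_volume(c(24, 24, 24), c(4, 4, 4), radius = 35)
  res <- sapply(c(90, 180, 360), function(nv) {
    geom <- test_geometry(angles = (seq_len(nv) - 1) * 360 / nv,
                          n_u = 48, n_v = 48, du = 4, dv = 4)
    relative_error(fdk_reconstruct(project_set(vol, geom), vol), vol)
  })
  expect_true(all(diff(res) < 0))
})

test_that("FDK of all-zero projections is zero and bad sampling warns", {
  geom <- test_geometry(angles = (0:89) * 4, n_u = 16, n_v = 16, du = 8,
                        dv = 8)
  ps <- projection_set(array(0, c(16, 16, 90)), geom)
  rec <- fdk_reconstruct(ps, grid_def(c(8, 8, 8), c(4, 4, 4)))
  expect_true(all(rec$data == 0))
  geom2 <- test_geometry(angles = (0:29) * 2, n_u = 16, n_v = 16, du = 8,
                         dv = 8)
  ps2 <- projection_set(array(0, c(16, 16, 30)), geom2)
  expect_warning(fdk_reconstruct(ps2, grid_def(c(8, 8, 8), c(4, 4, 4))),
                 "badly sampled")
})

test_that("ramp filter kernel equals the discrete analytic form", {
  du <- 1.55
  h <- ramp_kernel(6, du)
  n <- -6:6
  expected <- ifelse(n == 0, 1 / (4 * du^2),
                     ifelse(n %% 2 == 0, 0, -1 / (pi^2 * n^2 * du^2)))
  expect_equal(h, expected, tolerance = 1e-14)
})
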