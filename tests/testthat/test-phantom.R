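test_that("phantom construction: tumor volume, determinism, empty tumor", {
  spec <- phantom_spec(c(64, 64, 32), c(3, 3, 3), tumor_diameter = 30)
  ph <- build_phantom(spec)
  vox <- sum(ph$tumor_mask$data)
  analytic <- (4 / 3) * pi * 15^3 / prod(spec$grid$spacing)
  expect_lt(abs(vox - analytic) / analytic, 0.02)
  ph2 <- build_phantom(spec)
  expect_identical(ph$volume$data, ph2$volume$data)
  ph0 <- build_phantom(phantom_spec(c(64, 64, 32), c(3, 3, 3),
                                    tumor_diameter = 0))
  expect_true(all(ph0$tumor_mask$data == 0))
  expect_true(all(ph$volume$data >= 0))
})

test_that("trajectories: sampling, periodicity, range extension, seeding", {
  tr <- make_trajectory("regular", duration_s = 20, fps = 11)
  expect_length(tr$a, 220)
  # periodic with the stated 4 s period
  expect_equal(tr$a[1:44], tr$a[45:88], tolerance = 1e-12)
  expect_true(all(tr$a >= 0 & tr$a <= 1))

  ext <- make_trajectory("X7", duration_s = 20, fps = 11, seed = 2)
  reg <- make_trajectory("X1", duration_s = 20, fps = 11)
  expect_gt(ext$si_peak * max(ext$a), reg$si_peak * max(reg$a))

  a1 <- make_trajectory("amp", duration_s = 20, fps = 11, seed = 9)$a
  a2 <- make_trajectory("amp", duration_s = 20, fps = 11, seed = 9)$a
  a3 <- make_trajectory("amp", duration_s = 20, fps = 11, seed = 10)$a
  expect_identical(a1, a2)
  expect_false(identical(a1, a3))
  expect_error(make_trajectory("nope"), "arg")
})

test_that("simulated scans carry consistent angles, truth, and motion", {
  inp <- tiny_study_inputs()
  sim <- inp$sim
  n <- length(inp$traj$a)
  expect_equal(dim(sim$projections$frames)[3], n)
  expect_equal(sim$projections$geometry$angles,
               (seq_len(n) - 1) * 360 / n, tolerance = 1e-12)

  # zero-amplitude trajectory: every frame equals the static projection
  traj0 <- inp$traj
  traj0$a[] <- 0
  sim0 <- simulate_scan(inp$phantom, traj0,
                        geometry_args = list(sad = 1000, sdd = 1500,
                                             n_u = 16L, n_v = 12L,
                                             du = 26, dv = 26))
  static <- forward_project(inp$phantom$volume, sim0$projections$geometry,
                            sim0$projections$geometry$angles[4])
  expect_equal(sim0$projections$frames[, , 4], static, tolerance = 1e-12)

  # tumor centroid travel between exhale and peak inhale matches the
  # configured SI peak within half a voxel
  ipeak <- which.max(inp$traj$a)
  iex <- which.min(inp$traj$a)
  dz <- sim$truth$centers[3, ipeak] - sim$truth$centers[3, iex]
  expected <- (inp$traj$a[ipeak] - inp$traj$a[iex]) * inp$traj$si_peak
  expect_lt(abs(abs(dz) - expected), 0.5 * inp$gd$spacing[3])
})

test_that("ground-truth fields are consistent and invertible", {
  inp <- tiny_study_inputs()
  i <- which.max(inp$traj$a)
  d <- sim_truth_dvf(inp$sim, i)
  vol <- sim_truth_volume(inp$sim, i)
  expect_equal(vol$data,
               warp_volume(inp$phantom$volume, d)$data, tolerance = 1e-12)
  # analytic construction is smooth enough for accurate inversion
  dinv <- invert_dvf(d, 3)
  expect_lt(attr(dinv, "residual"), 0.5)
  # disjoint-angle protocol: a 90.27-degree offset shifts every angle
  traj_s <- make_trajectory("regular", duration_s = 8, fps = 1)
  simoff <- simulate_scan(inp$phantom, traj_s,
                          geometry_args = list(sad = 1000, sdd = 1500,
                                               n_u = 16L, n_v = 12L,
                                               du = 26, dv = 26),
                          angle_offset = 90.27)
  expect_equal(simoff$projections$geometry$angles[1], 90.27)
})

test_that("Poisson noise perturbs projections only when requested", {
  inp <- tiny_study_inputs()
  traj_s <- make_trajectory("regular", duration_s = 5, fps = 1)
  ga <- list(sad = 1000, sdd = 1500, n_u = 16L, n_v = 12L, du = 26, dv = 26)
  set.seed(1)
  clean <- simulate_scan(inp$phantom, traj_s, geometry_args = ga)
  set.seed(1)
  noisy <- simulate_scan(inp$phantom, traj_s, geometry_args = ga,
                         noise = "poisson", i0 = 1e4)
  expect_false(identical(clean$projections$frames, noisy$projections$frames))
  expect_lt(mean(abs(noisy$projections$frames - clean$projections$frames)),
            0.1)
})
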