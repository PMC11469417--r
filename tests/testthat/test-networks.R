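test_that("coordinate network renders deterministically; zero head is flat", {
  set.seed(21)
  gd <- grid_def(c(12, 12, 12), c(4, 4, 4))
  inr <- spatial_inr(gd, n_levels = 4, table_log2 = 10, base_resolution = 4,
                     growth = 1.5, hidden = c(16, 16))
  v1 <- render_volume(inr, gd)
  v2 <- render_volume(inr, gd)
  expect_identical(v1$data, v2$data)
  expect_true(all(is.finite(v1$data)))

  # zero all MLP weights: the volume is the softplus of the output bias
  inr0 <- inr
  inr0$params[(inr0$n_table + 1):length(inr0$params)] <- 0
  v0 <- render_volume(inr0, gd)
  expect_equal(max(abs(v0$data - log(2))), 0, tolerance = 1e-12)

  big <- grid_def(c(12, 12, 12), c(40, 40, 40))
  expect_error(render_volume(inr, big), "bounds")
})

test_that("network parameter gradients agree with finite differences", {
  set.seed(22)
  gd <- grid_def(c(8, 8, 8), c(4, 4, 4))
  inr <- spatial_inr(gd, n_levels = 3, table_log2 = 9, base_resolution = 3,
                     growth = 1.6, hidden = 8)
  gv <- rnorm(prod(gd$dims))
  gp <- rtcbct:::inr_backward(inr, gd, gv)
  obj <- function(p) {
    i2 <- inr; i2$params <- p
    sum(render_volume(i2, gd)$data * array(gv, gd$dims))
  }
  ii <- sample(which(abs(gp) > 1e-4), 5)
  for (i in ii) {
    e <- 1e-6
    p1 <- inr$params; p1[i] <- p1[i] + e
    p2 <- inr$params; p2[i] <- p2[i] - e
    fd <- (obj(p1) - obj(p2)) / (2 * e)
    expect_equal(gp[i], fd, tolerance = 1e-4)
  }
})

test_that("a short image-domain fit reproduces a sphere label", {
  set.seed(23)
  label <- sphere_volume(c(20, 20, 20), c(5, 5, 5), radius = 35,
                         value = 0.02)
  gd <- grid_def(c(20, 20, 20), c(5, 5, 5))
  inr <- spatial_inr(gd, n_levels = 6, table_log2 = 12, base_resolution = 4,
                     growth = 1.5, hidden = 16)
  opt <- rtcbct:::adam_init(length(inr$params))
  lab <- as.numeric(label$data)
  for (ep in 1:300) {
    fw <- rtcbct:::inr_forward(inr, gd)
    g <- 2 * (fw$values - lab) / length(lab)
    gp <- rtcbct:::inr_grad(inr, gd, g, cache = fw$cache)
    opt <- rtcbct:::adam_step(opt, gp, 4e-3)
    inr$params <- inr$params + opt$delta
  }
  fitvol <- render_volume(inr, gd)
  expect_lt(relative_error(fitvol, label), 0.1)
})

test_that("motion encoder contract: nine outputs, determinism, NaN guard", {
  set.seed(24)
  enc <- suppressMessages(motion_encoder(input_h = 24, input_w = 32))
  frame <- matrix(abs(rnorm(48 * 64)), 48, 64)
  s1 <- encode_projection(enc, frame)
  expect_equal(dim(s1), c(9L, 1L))
  expect_true(all(is.finite(s1)))
  expect_identical(s1, encode_projection(enc, frame))
  bad <- frame; bad[3, 3] <- NaN
  expect_error(encode_projection(enc, bad), "NaN")

  # eval mode must use running statistics: a frame's scores do not depend
  # on its batch companions
  batch <- array(abs(rnorm(48 * 64 * 3)), c(48, 64, 3))
  batch[, , 1] <- frame
  sb <- encode_projection(enc, batch)
  expect_equal(sb[, 1], s1[, 1], tolerance = 1e-12)

  # train mode updates running stats, eval mode leaves them alone
  x <- rtcbct:::preprocess_frames(enc, batch)
  r1 <- rtcbct:::encoder_forward(enc, x, 3, train = TRUE)
  expect_false(identical(r1$rstats, enc$rstats))
  r2 <- rtcbct:::encoder_forward(enc, x, 3, train = FALSE)
  expect_identical(r2$rstats, enc$rstats)
})

test_that("encoder gradients agree with finite differences", {
  set.seed(25)
  enc <- suppressMessages(motion_encoder(input_h = 12, input_w = 16))
  B <- 2
  x <- abs(rnorm(12 * 16 * B))
  gs <- matrix(rnorm(18), 9, B)
  fw <- rtcbct:::encoder_forward(enc, x, B, train = TRUE)
  bw <- rtcbct:::encoder_backward(enc, x, B, fw, gs, train = TRUE,
                                  need_ginput = TRUE)
  obj_p <- function(p) {
    e2 <- enc; e2$params <- p
    sum(rtcbct:::encoder_forward(e2, x, B, train = TRUE)$scores * gs)
  }
  ii <- sample(which(abs(bw$gparams) > 1e-4), 5)
  for (i in ii) {
    e <- 1e-6
    p1 <- enc$params; p1[i] <- p1[i] + e
    p2 <- enc$params; p2[i] <- p2[i] - e
    expect_equal(bw$gparams[i], (obj_p(p1) - obj_p(p2)) / (2 * e),
                 tolerance = 1e-4)
  }
  obj_x <- function(xx)
    sum(rtcbct:::encoder_forward(enc, xx, B, train = TRUE)$scores * gs)
  jj <- sample(which(abs(bw$ginput) > 1e-4), 4)
  for (i in jj) {
    e <- 1e-6
    x1 <- x; x1[i] <- x1[i] + e
    x2 <- x; x2[i] <- x2[i] - e
    expect_equal(bw$ginput[i], (obj_x(x1) - obj_x(x2)) / (2 * e),
                 tolerance = 1e-4)
  }
})

test_that("gradients from the projection loss reach every component", {
  # toy scene: one frame, tiny grid; finite nonzero gradients must arrive
  # at the hash tables, MLP, B-spline coefficients and the CNN
  set.seed(26)
  gd <- grid_def(c(10, 10, 10), c(6, 6, 6))
  geom <- test_geometry(angles = 40, n_u = 12, n_v = 12, du = 12, dv = 12)
  inr <- spatial_inr(gd, n_levels = 3, table_log2 = 9, base_resolution = 3,
                     growth = 1.5, hidden = 8)
  enc <- suppressMessages(motion_encoder(input_h = 12, input_w = 12))
  enc$intensity_scale <- 1
  basis <- motion_basis(gd)
  basis$coef <- rnorm(length(basis$coef), 0, 0.05)
  E <- evaluate_basis(basis, gd)

  fw <- rtcbct:::inr_forward(inr, gd)
  iref <- volume_grid(array(fw$values, gd$dims), gd$spacing, gd$origin)
  # two frames: batch statistics of the 1x1 deep feature maps need more
  # than one sample
  meas <- array(abs(rnorm(288)), c(12, 12, 2))
  x <- rtcbct:::preprocess_frames(enc, meas)
  cf <- rtcbct:::encoder_forward(enc, x, 2, train = TRUE)
  d <- compose_dvf(cf$scores[, 1], E, gd)
  wv <- warp_volume(iref, d)
  drr <- forward_project(wv, geom, 40)
  gdrr <- 2 * (drr - meas[, , 1]) / (2 * 144)
  gvol <- backproject_gradient(gdrr, gd, geom, 40)
  bwp <- rtcbct:::cpp_warp_backward(iref$data, d$displacement, gvol,
                                    gd$dims, gd$spacing, gd$origin,
                                    TRUE, TRUE)
  g_inr <- rtcbct:::inr_grad(inr, gd, bwp$gvol, cache = fw$cache)
  expect_true(any(g_inr[seq_len(inr$n_table)] != 0))          # hash tables
  expect_true(any(g_inr[-seq_len(inr$n_table)] != 0))         # MLP
  gmat <- matrix(bwp$gdvf, ncol = 3)
  g_E <- matrix(0, nrow(E), 9)
  gsc <- matrix(0, 9, 2)
  for (k in 1:3) {
    j <- rtcbct:::score_index(1:3, k)
    gsc[j, 1] <- crossprod(E[, j, drop = FALSE], gmat[, k])
    g_E[, j] <- gmat[, k] %o% cf$scores[j, 1]
  }
  g_bas <- rtcbct:::basis_adjoint(basis, gd, g_E)
  expect_true(any(g_bas != 0))                                # B-splines
  bw <- rtcbct:::encoder_backward(enc, x, 2, cf, gsc, train = TRUE)
  expect_true(any(bw$gparams != 0))                           # CNN
  expect_true(all(is.finite(c(g_inr, g_bas, as.numeric(bw$gparams)))))
})
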