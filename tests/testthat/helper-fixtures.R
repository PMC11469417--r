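# Shared builders for the test suite. Everything is generated in code at
# run time; fixture sizes are kept small so single tests stay in the
# second range.

# smooth random volume (blurred white noise), convenient for warp tests
smooth_volume <- function(dims = c(16, 16, 16), spacing = c(2, 2, 2),
                          sigma = 2) {
  v <- rtcbct:::cpp_gaussian_blur3(rnorm(prod(dims)), as.integer(dims),
                                   sigma, as.integer(ceiling(3 * sigma)))
  volume_grid(array(v, dims), spacing)
}

# centered sphere of given radius (mm) and value on a grid
sphere_volume <- function(dims = c(24, 24, 24), spacing = c(4, 4, 4),
                          radius = 30, value = 0.02) {
  gd <- grid_def(dims, spacing)
  ax <- function(a) gd$origin[a] + (seq_len(dims[a]) - 1) * spacing[a]
  r2 <- outer(outer(ax(1)^2, ax(2)^2, `+`), ax(3)^2, `+`)
  volume_grid(array(value * (r2 <= radius^2), dims), spacing)
}

test_geometry <- function(angles = 0, n_u = 33, n_v = 33, du = 3, dv = 3) {
  scan_geometry(sad = 1000, sdd = 1500, n_u = n_u, n_v = n_v,
                du = du, dv = dv, angles = angles)
}

# smooth sinusoidal SI displacement field (amplitude mm, period mm)
sinusoid_dvf <- function(dims = c(24, 24, 24), spacing = c(4, 4, 4),
                         amplitude = 5, period = 100) {
  gd <- grid_def(dims, spacing)
  zs <- gd$origin[3] + (seq_len(dims[3]) - 1) * spacing[3]
  dz <- array(rep(amplitude * sin(2 * pi * zs / period),
                  each = dims[1] * dims[2]), dims)
  d <- array(0, c(dims, 3))
  d[, , , 3] <- dz
  dvf(d, gd)
}

# tiny end-to-end training fixture shared by trainer/inference tests;
# built once per test run
tiny_fit_env <- new.env()

tiny_study_inputs <- function() {
  if (is.null(tiny_fit_env$inputs)) {
    set.seed(42)
    gd <- grid_def(c(32, 32, 16), c(6, 6, 6))
    ph <- build_phantom(phantom_spec(gd$dims, gd$spacing,
                                     tumor_diameter = 24))
    traj <- make_trajectory("freq", duration_s = 30, fps = 2, seed = 5)
    sim <- simulate_scan(ph, traj,
                         geometry_args = list(sad = 1000, sdd = 1500,
                                              n_u = 32L, n_v = 24L,
                                              du = 13, dv = 13))
    tiny_fit_env$inputs <- list(gd = gd, phantom = ph, traj = traj,
                                sim = sim)
  }
  tiny_fit_env$inputs
}

tiny_schedule <- function(epochs = c(20, 20, 40, 20, 20, 30, 30)) {
  # epoch counts ~1/30 of the reference schedule; scale the rates part-way
  # up (see training_schedule) so the tiny fixture makes visible progress
  sch <- training_schedule(lr_scale = 10)
  sch$epochs <- epochs
  sch
}

tiny_inr_options <- list(n_levels = 5, table_log2 = 11, base_resolution = 4,
                         growth = 1.5, hidden = 16)

tiny_fit <- function() {
  if (is.null(tiny_fit_env$fit)) {
    inp <- tiny_study_inputs()
    tiny_fit_env$fit <- rtcbct(
      inp$sim$projections, inp$gd, schedule = tiny_schedule(),
      batch_size = 4, inr_options = tiny_inr_options,
      encoder_options = list(input_h = 24L, input_w = 32L),
      seed = 7, verbose = FALSE)
  }
  tiny_fit_env$fit
}
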