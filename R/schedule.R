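#' Progressive multiresolution training schedule
#'
#' Seven ordered stages over two spatial resolutions. The defaults are the
#' reference configuration:
#'
#' | stage | epochs | res (mm) | lr INR | lr encoder | lr B-spline | losses | augmentation |
#' |-------|--------|----------|--------|------------|-------------|--------|--------------|
#' | I-a   | 400    | 4        | 4e-4   | 0          | 0           | image  | off |
#' | I-b   | 700    | 4        | 4e-5   | 0          | 0           | projection, tv | off |
#' | I-c   | 1700   | 4        | 1e-5   | 1e-3       | 1e-3        | projection, tv, mbc, zero_mean, self_consistency | off |
#' | II-a  | 1000   | 2        | 1e-3   | 0          | 0           | image  | off |
#' | II-b  | 1000   | 2        | 4e-4   | 0          | 0           | projection, tv, augmentation | angle_only |
#' | II-c  | 1000   | 2        | 1e-4   | 1e-4       | 1e-4        | projection, tv, mbc, zero_mean, self_consistency, augmentation | angle_only |
#' | II-d  | 1000   | 2        | 0      | 1e-4       | 0           | augmentation | motion_and_angle |
#'
#' A zero learning rate freezes the component for the stage (its parameters
#' are bitwise unchanged). An "epoch" is one optimizer step on one mini-batch
#' of projections drawn without replacement per cycle; the stage counts above
#' are iteration counts, not passes over the full scan.
#'
#' When the epoch counts are scaled down, the learning rates are scaled up
#' by `lr_scale` (default `1/epoch_scale`) so that the total optimizer
#' displacement per stage — the product of step size and step count —
#' matches the full-length schedule; at `epoch_scale = 1` the reference
#' rates are used unchanged.
#'
#' @param epoch_scale Multiplier applied (with `ceiling`) to every stage's
#'   epoch count; `1/4` gives the scaled-down profile used for desk-size
#'   studies.
#' @param lr_scale Multiplier on all learning rates; defaults to
#'   `1/epoch_scale`.
#' @param resolutions Stage-I and stage-II isotropic voxel sizes (mm).
#' @return A data frame of class `training_schedule` with list-columns
#'   `losses` (character vectors) and `augmentation`.
#' @export
training_schedule <- function(epoch_scale = 1, lr_scale = 1 / epoch_scale,
                              resolutions = c(4, 2)) {
  st <- data.frame(
    stage = c("I-a", "I-b", "I-c", "II-a", "II-b", "II-c", "II-d"),
    epochs = ceiling(c(400, 700, 1700, 1000, 1000, 1000, 1000) * epoch_scale),
    resolution = c(resolutions[1], resolutions[1], resolutions[1],
                   resolutions[2], resolutions[2], resolutions[2],
                   resolutions[2]),
    lr_inr = lr_scale * c(4e-4, 4e-5, 1e-5, 1e-3, 4e-4, 1e-4, 0),
    lr_encoder = lr_scale * c(0, 0, 1e-3, 0, 0, 1e-4, 1e-4),
    lr_bspline = lr_scale * c(0, 0, 1e-3, 0, 0, 1e-4, 0),
    stringsAsFactors = FALSE)
  st$losses <- list(
    "image",
    c("projection", "tv"),
    c("projection", "tv", "mbc", "zero_mean", "self_consistency"),
    "image",
    c("projection", "tv", "augmentation"),
    c("projection", "tv", "mbc", "zero_mean", "self_consistency",
      "augmentation"),
    "augmentation")
  st$augmentation <- c("off", "off", "off", "off", "angle_only", "angle_only",
                       "motion_and_angle")
  class(st) <- c("training_schedule", "data.frame")
  st
}

#' @export
print.training_schedule <- function(x, ...) {
  cat("Progressive training schedule:\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-5s %5d epochs @ %g mm | lr INR %g, enc %g, B-spl %g | %s%s\n",
                x$stage[i], x$epochs[i], x$resolution[i], x$lr_inr[i],
                x$lr_encoder[i], x$lr_bspline[i],
                paste(x$losses[[i]], collapse = "+"),
                if (x$augmentation[i] == "off") ""
                else paste0(" [", x$augmentation[i], "]")))
  invisible(x)
}

#' Scaled-down study profile
#'
#' The problem sizes used by the package's simulation studies and test suite:
#' a 96x96x48 voxel grid at 2 mm, 64x48-pixel detector frames, a 240-frame
#' 360-degree training scan, stage epochs divided by 4, a mini-batch of 4
#' frames, and a slimmed coordinate-network configuration (8 hash levels,
#' 2^15 tables, one 16-unit hidden layer). These are fixed study conditions,
#' not tuning knobs; the full-scale profile doubles the grid, uses
#' 256x192-pixel frames at 1.55 mm pitch, 660 frames, a batch of 32, and the
#' full network configuration.
#'
#' @return A list with elements `grid` (fine grid definition), `geometry_args`
#'   (detector/geometry parameters sans angles), `n_train_frames`,
#'   `n_test_frames`, `duration_s`, `schedule`, `batch_size`,
#'   `inr_options`, `encoder_options` (the encoder reads desk frames at
#'   their native 64x48 size).
#' @export
desk_profile <- function() {
  list(grid = grid_def(c(96L, 96L, 48L), c(2, 2, 2)),
       geometry_args = list(sad = 1000, sdd = 1500, n_u = 64L, n_v = 48L,
                            du = 4.65, dv = 4.65, detector_offset_u = 0),
       n_train_frames = 240L,
       n_test_frames = 120L,
       duration_s = 60,
       schedule = training_schedule(epoch_scale = 1 / 4),
       batch_size = 4L,
       inr_options = list(n_levels = 8, n_features = 2, table_log2 = 15,
                          base_resolution = 4, growth = 1.6,
                          hidden = 16),
       encoder_options = list(input_h = 48L, input_w = 64L))
}
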