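#' Evaluate a fitted model against a simulated scan
#'
#' Runs single-projection inference on every frame of a [simulate_scan()]
#' result and scores it against the analytic ground truth: relative error
#' and SSIM of the solved volumes, and center-of-mass error / Dice of the
#' propagated tumor contour.
#'
#' @param fit A fitted [rtcbct()] model.
#' @param sim A `cbct_sim` test scan.
#' @param ref_mask Reference tumor contour on the model grid (a
#'   [volume_grid()], e.g. from [segment_tumor()] on `fit$reference`).
#' @return Data frame with one row per frame: `come` (mm), `dsc`, `ssim`,
#'   `re`.
#' @export
evaluate_scan <- function(fit, sim, ref_mask) {
  frames <- sim$projections$frames
  np <- dim(frames)[3]
  scores <- encode_projection(fit$encoder, frames)
  out <- data.frame(frame = seq_len(np), come = NA_real_, dsc = NA_real_,
                    ssim = NA_real_, re = NA_real_)
  for (i in seq_len(np)) {
    d <- compose_fast(scores[, i], fit$basis_fields, fit$grid)
    vol <- warp_volume(fit$reference, d)
    truth_vol <- sim_truth_volume(sim, i)
    mask <- propagate_contour(ref_mask, d)
    truth_mask <- sim_truth_mask(sim, i)
    cen <- mask_centroid(mask)
    out$come[i] <- if (anyNA(cen)) NA_real_ else
      sqrt(sum((cen - sim$truth$centers[, i])^2))
    out$dsc[i] <- dsc(mask, truth_mask)
    out$ssim[i] <- ssim_volume(vol, truth_vol)
    out$re[i] <- relative_error(vol, truth_vol)
  }
  out
}

#' Scaled-down dynamic CBCT simulation study
#'
#' The package's end-to-end study: build the analytic thorax phantom on the
#' desk-profile grid (96x96x48 at 2 mm, 30-mm tumor), simulate a 240-frame
#' 360-degree pre-treatment scan under one breathing scenario, train the
#' full model with the quarter-epoch schedule, then test against all seven
#' scenarios simulated at gantry angles offset by 90.27 degrees (so no test
#' frame shares both angle and motion state with training). Reported per
#' scenario and overall: mean tumor center-of-mass error, Dice, SSIM and
#' relative error over the test frames.
#'
#' @param train_kind Training scenario (default `"X3"`, the
#'   frequency-varying mid-complexity trajectory).
#' @param test_kinds Test scenarios (default all seven).
#' @param profile Study profile, see [desk_profile()].
#' @param seed Master seed for simulation and training.
#' @param angle_offset_test Gantry offset of the test scans (degrees).
#' @param fit Optional pre-trained model (skips training; the phantom and
#'   test scans are still rebuilt from `seed`).
#' @param verbose Print progress.
#' @return Object of class `rtcbct_study`: `per_scenario` data frame,
#'   `overall` named means, the `fit`, and the per-frame `details`.
#' @export
run_simulation_study <- function(train_kind = "X3",
                                 test_kinds = paste0("X", 1:7),
                                 profile = desk_profile(), seed = 1,
                                 angle_offset_test = 90.27, fit = NULL,
                                 verbose = TRUE) {
  set.seed(seed)
  phant <- build_phantom(phantom_spec(profile$grid$dims,
                                      profile$grid$spacing))
  fps_train <- profile$n_train_frames / profile$duration_s
  traj_train <- make_trajectory(train_kind, profile$duration_s, fps_train,
                                seed = seed + 1000L)
  if (is.null(fit)) {
    if (verbose) message(sprintf("simulating %d-frame training scan (%s)...",
                                 profile$n_train_frames, train_kind))
    sim_train <- simulate_scan(phant, traj_train,
                               geometry_args = profile$geometry_args)
    fit <- rtcbct(sim_train$projections, profile$grid,
                  schedule = profile$schedule,
                  batch_size = profile$batch_size,
                  inr_options = profile$inr_options,
                  encoder_options = profile$encoder_options,
                  seed = seed, verbose = verbose)
  }
  thr <- mean(phant$spec$attenuation[c("lung", "tumor")])
  ref_mask <- segment_tumor(fit$reference, threshold = thr)
  if (sum(ref_mask$data) == 0)
    warning("no tumor found in the reconstructed reference volume")

  fps_test <- profile$n_test_frames / profile$duration_s
  details <- list()
  rows <- list()
  for (k in seq_along(test_kinds)) {
    kind <- test_kinds[k]
    traj <- make_trajectory(kind, profile$duration_s, fps_test,
                            seed = seed + 2000L + k)
    sim <- simulate_scan(phant, traj,
                         geometry_args = profile$geometry_args,
                         angle_offset = angle_offset_test)
    if (verbose) message(sprintf("evaluating test scenario %s (%d frames)...",
                                 kind, profile$n_test_frames))
    res <- evaluate_scan(fit, sim, ref_mask)
    res$scenario <- kind
    details[[k]] <- res
    rows[[k]] <- data.frame(
      scenario = kind,
      come_mean = mean(res$come, na.rm = TRUE),
      come_sd = sd(res$come, na.rm = TRUE),
      dsc_mean = mean(res$dsc), ssim_mean = mean(res$ssim),
      re_mean = mean(res$re), n_empty = sum(is.na(res$come)))
  }
  per_scenario <- do.call(rbind, rows)
  all_frames <- do.call(rbind, details)
  overall <- c(come = mean(all_frames$come, na.rm = TRUE),
               come_sd = sd(all_frames$come, na.rm = TRUE),
               dsc = mean(all_frames$dsc),
               ssim = mean(all_frames$ssim),
               re = mean(all_frames$re))
  structure(list(per_scenario = per_scenario, overall = overall,
                 train_kind = train_kind, fit = fit,
                 details = all_frames, seed = seed),
            class = "rtcbct_study")
}

#' @export
print.rtcbct_study <- function(x, ...) {
  cat(sprintf("Simulation study: trained on %s, tested on %d scenarios\n",
              x$train_kind, nrow(x$per_scenario)))
  print(x$per_scenario, row.names = FALSE, digits = 4)
  cat(sprintf(paste0("\noverall: COME %.2f +- %.2f mm | DSC %.3f | ",
                     "SSIM %.4f | RE %.3f\n"),
              x$overall[["come"]], x$overall[["come_sd"]],
              x$overall[["dsc"]], x$overall[["ssim"]], x$overall[["re"]]))
  invisible(x)
}
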