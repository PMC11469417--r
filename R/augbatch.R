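#' Build an augmented DRR batch with score targets
#'
#' The training-sample generator behind the encoder-hardening stages, exposed
#' for inspection and testing. For each input frame the currently solved
#' motion-basis scores are taken as the motion state; in
#' `"motion_and_angle"` mode they are additionally rescaled by
#' [augment_scores()]. The corresponding dynamic volume is rendered by
#' deforming the reference anatomy and projected at a random (or supplied)
#' gantry angle, yielding a DRR whose correct encoder output is the target
#' score vector.
#'
#' @param fit A fitted (or partially trained) [rtcbct()] model.
#' @param frames Array `(n_v, n_u, B)` (or matrix) of projections whose
#'   solved scores seed the batch.
#' @param cfg An [augmentation_config()] with `mode` `"angle_only"` or
#'   `"motion_and_angle"`.
#' @param angles Optional gantry angles (degrees); default uniform on
#'   `[0, 360)`.
#' @return List with `drrs` (array `(n_v, n_u, B)`), `targets` (9 x B),
#'   `angles`.
#' @export
make_augmented_batch <- function(fit, frames, cfg = augmentation_config(
                                   mode = "angle_only"), angles = NULL) {
  if (cfg$mode == "off") stop("augmentation mode is 'off'")
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  B <- dim(frames)[3]
  geom <- fit$geometry
  solved <- encode_projection(fit$encoder, frames)
  targets <- if (cfg$mode == "motion_and_angle")
    augment_scores(solved, cfg) else solved
  if (is.null(angles)) angles <- runif(B, 0, 360)
  drrs <- array(0, c(geom$n_v, geom$n_u, B))
  for (b in seq_len(B)) {
    d <- compose_fast(targets[, b], fit$basis_fields, fit$grid)
    drrs[, , b] <- forward_project(warp_volume(fit$reference, d), geom,
                                   angles[b])
  }
  list(drrs = drrs, targets = targets, angles = angles)
}
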