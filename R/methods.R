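#' @export
print.rtcbct <- function(x, ...) {
  cat("Dynamic CBCT reconstruction with real-time motion estimation\n")
  cat(sprintf("  trained on %d projections (%dx%d px), grid %s @ %g mm\n",
              x$n_projections, x$geometry$n_v, x$geometry$n_u,
              paste(x$grid$dims, collapse = "x"), x$grid$spacing[1]))
  cat(sprintf("  stages: %s\n", paste(x$schedule$stage, collapse = " ")))
  if (!is.null(x$history)) {
    last <- tail(x$history, 1)
    cat(sprintf("  final stage loss: %.4g\n", last$total))
  }
  invisible(x)
}

#' @export
summary.rtcbct <- function(object, ...) {
  h <- object$history
  per_stage <- do.call(rbind, lapply(split(h, h$stage), function(d)
    data.frame(stage = d$stage[1], epochs = nrow(d),
               first_loss = d$total[1], final_loss = tail(d$total, 1))))
  per_stage <- per_stage[match(object$schedule$stage, per_stage$stage), ]
  sc <- object$solved_scores
  res <- list(stages = per_stage,
              score_range = t(apply(sc, 1, range)),
              score_sd = apply(sc, 1, sd),
              reference_range = range(object$reference$data),
              n_projections = object$n_projections)
  class(res) <- "summary.rtcbct"
  res
}

#' @export
print.summary.rtcbct <- function(x, ...) {
  cat("Training summary (per stage):\n")
  print(x$stages, row.names = FALSE)
  cat(sprintf("\nReference volume range: [%.4g, %.4g] mm^-1\n",
              x$reference_range[1], x$reference_range[2]))
  cat("Solved score spread (SD per motion-basis channel):\n")
  lvl <- rep(1:3, each = 3); k <- rep(c("x", "y", "z"), 3)
  for (j in 1:9)
    cat(sprintf("  level %d, %s: %.3f\n", lvl[j], k[j], x$score_sd[j]))
  invisible(x)
}

#' Solved motion-basis scores
#'
#' `coef()` on a fitted model returns the 9 x Np matrix of motion-basis
#' scores solved for the training projections (the temporal coefficients of
#' the low-rank motion model). `type = "basis"` instead returns the flat
#' B-spline coefficient vector of the spatial components.
#'
#' @param object A fitted [rtcbct()] model.
#' @param type `"scores"` or `"basis"`.
#' @param ... Unused.
#' @return Matrix `(9, Np)` of scores or the numeric basis coefficients.
#' @export
coef.rtcbct <- function(object, type = c("scores", "basis"), ...) {
  type <- match.arg(type)
  if (type == "scores") object$solved_scores else object$basis$coef
}

#' Real-time inference from single projections
#'
#' For each input frame the motion encoder (in eval mode, batch-norm running
#' statistics) produces nine motion-basis scores; the displacement field is
#' their basis combination, and the volumetric image is the warped reference.
#' The result is a pure function of (model, frame) — no angle input is
#' needed, the encoder is angle-agnostic by training.
#'
#' @param object A fitted [rtcbct()] model.
#' @param frames Matrix `(n_v, n_u)` or array `(n_v, n_u, B)` of post-log
#'   projections.
#' @param type What to return: `"scores"` only, `"dvf"` (scores + DVFs), or
#'   `"volume"` (scores + DVFs + warped volumes).
#' @param ... Unused.
#' @return A list with `scores` (9 x B matrix) and, depending on `type`,
#'   `dvf` (list of [dvf()]) and `volume` (list of [volume_grid()]). Wall
#'   time per frame is recorded in attribute `ms_per_frame` (logged, never a
#'   contract).
#' @export
predict.rtcbct <- function(object, frames,
                           type = c("volume", "dvf", "scores"), ...) {
  type <- match.arg(type)
  if (is.null(object$encoder$params) || all(object$basis$coef == 0))
    warning("model looks untrained; predictions are not meaningful")
  t0 <- proc.time()[3]
  scores <- encode_projection(object$encoder, frames)
  out <- list(scores = scores)
  if (type %in% c("dvf", "volume")) {
    B <- ncol(scores)
    out$dvf <- lapply(seq_len(B), function(b)
      compose_dvf(scores[, b], object$basis_fields, object$grid))
    if (type == "volume")
      out$volume <- lapply(out$dvf, function(d)
        warp_volume(object$reference, d))
  }
  attr(out, "ms_per_frame") <- 1000 * (proc.time()[3] - t0) / ncol(scores)
  out
}

#' Projection-domain residuals of the fitted dynamic sequence
#'
#' For a subset of training frames, re-renders the DRR of the solved dynamic
#' volume at the acquisition angle and returns measured - rendered.
#'
#' @param object A fitted [rtcbct()] model.
#' @param projections The [projection_set()] the model was trained on (the
#'   fit does not retain the raw frames).
#' @param frames Indices of training frames (default: 8 spread over the scan).
#' @param ... Unused.
#' @return Array `(n_v, n_u, length(frames))` of residuals.
#' @export
residuals.rtcbct <- function(object, projections, frames = NULL, ...) {
  stopifnot(inherits(projections, "projection_set"))
  np <- object$n_projections
  if (n_frames(projections) != np)
    stop("projection set does not match the training scan")
  if (is.null(frames))
    frames <- unique(round(seq(1, np, length.out = 8)))
  geom <- object$geometry
  res <- array(0, c(geom$n_v, geom$n_u, length(frames)))
  for (i in seq_along(frames)) {
    b <- frames[i]
    d <- compose_dvf(object$solved_scores[, b], object$basis_fields,
                     object$grid)
    vol <- warp_volume(object$reference, d)
    drr <- forward_project(vol, geom, geom$angles[b])
    res[, , i] <- projections$frames[, , b] - drr
  }
  res
}

#' Training diagnostics plot
#'
#' Left: total loss per epoch on a log scale, stage boundaries marked.
#' Right: solved motion-basis score traces over the training scan.
#'
#' @param x A fitted [rtcbct()] model.
#' @param ... Passed to [matplot()] for the score panel.
#' @export
plot.rtcbct <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  h <- x$history
  plot(seq_len(nrow(h)), pmax(h$total, 1e-12), type = "l", log = "y",
       xlab = "epoch (cumulative)", ylab = "total loss",
       main = "training loss")
  bounds <- cumsum(x$schedule$epochs)
  abline(v = head(bounds, -1), col = "grey70", lty = 3)
  matplot(t(x$solved_scores), type = "l", lty = 1,
          xlab = "projection index", ylab = "score",
          main = "solved motion scores", ...)
  invisible(x)
}
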