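#' Fit the joint dynamic-reconstruction / motion-estimation model
#'
#' Reconstructs a dynamic CBCT sequence from a single pre-treatment cone-beam
#' scan and simultaneously trains a motion encoder for real-time inference.
#' The dynamic anatomy is factorized as
#' `I(x, p) = Iref(x + d(x, p))` with
#' `d_k(x, p) = sum_i w[i,k](p) * e_{i,k}(x)`:
#' a static reference volume `Iref` (hash-encoded coordinate network), nine
#' B-spline motion basis components `e_{i,k}`, and per-projection scores
#' `w[i,k](p)` produced by a convolutional encoder reading the raw
#' projection. Training follows the progressive multiresolution
#' [training_schedule()]: the reference volume is warm-started from an FDK
#' reconstruction, the motion model joins at stage I-c, and the final stage
#' hardens the encoder with motion- and angle-augmented DRRs so that it
#' generalizes to unseen motion states and gantry angles.
#'
#' All randomness (initialization, mini-batch draws, augmentation) is driven
#' by R's RNG seeded with `seed`; two runs with the same seed and
#' configuration are bitwise reproducible.
#'
#' @param projections A [projection_set()]: the pre-treatment scan.
#' @param grid Grid definition or [volume_grid()]: the reconstruction grid at
#'   the finest (stage II) resolution.
#' @param schedule A [training_schedule()].
#' @param weights A [loss_weights()].
#' @param batch_size Projections per optimizer step.
#' @param basis_control Level-1 control-point counts for [motion_basis()].
#' @param inr_options Named list overriding [spatial_inr()] arguments.
#' @param encoder_options Named list overriding [motion_encoder()] arguments.
#' @param image_subsample Voxel samples per step for image-domain stages on
#'   grids larger than this (stochastic estimate of the full-grid loss).
#' @param seed Master seed controlling initialization, batching and
#'   augmentation.
#' @param keep_checkpoints Keep a parameter snapshot after every stage.
#' @param verbose Print stage progress.
#' @return An object of class `rtcbct`; see [predict.rtcbct()],
#'   [coef.rtcbct()], [plot.rtcbct()].
#' @export
rtcbct <- function(projections, grid, schedule = training_schedule(),
                   weights = loss_weights(), batch_size = 32,
                   basis_control = c(6, 6, 4),
                   inr_options = list(), encoder_options = list(),
                   image_subsample = 131072L, seed = 1,
                   keep_checkpoints = TRUE, verbose = TRUE) {
  stopifnot(inherits(projections, "projection_set"))
  cl <- match.call()
  set.seed(seed)
  geom <- projections$geometry
  np <- n_frames(projections)
  batch_size <- min(batch_size, np)

  fine <- if (inherits(grid, "volume_grid"))
    grid_def(dim(grid$data), grid$spacing, grid$origin) else grid
  factor <- schedule$resolution[1] / schedule$resolution[nrow(schedule)]
  coarse <- coarsen_grid(fine, factor)

  inr <- do.call(spatial_inr, c(list(grid = fine), inr_options))
  enc <- suppressMessages(do.call(motion_encoder, encoder_options))
  enc$intensity_scale <- max(projections$frames)
  basis <- motion_basis(fine, base_control = basis_control)

  if (verbose) message(sprintf(
    "FDK warm-start label on %s grid from %d views...",
    paste(coarse$dims, collapse = "x"), np))
  fdk <- fdk_reconstruct(projections, coarse)
  fdk$data[fdk$data < 0] <- 0

  state <- list(inr = inr, enc = enc, basis = basis)
  history <- vector("list", sum(schedule$epochs))
  hptr <- 0L
  history_acc <- function(h) { hptr <<- hptr + 1L; history[[hptr]] <<- h }
  checkpoints <- list()
  label <- fdk          # image-domain label for the current resolution
  solved_targets <- NULL

  for (si in seq_len(nrow(schedule))) {
    stg <- schedule[si, ]
    gd <- if (stg$resolution == schedule$resolution[1]) coarse else fine
    # stage II-a: re-warm-start against the upsampled stage-I solution
    if (stg$stage == "II-a") {
      iref_lo <- render_volume(state$inr, coarse)
      up <- cpp_resample_volume(as.numeric(iref_lo$data), coarse$dims,
                                coarse$spacing, coarse$origin,
                                fine$dims, fine$spacing, fine$origin)
      label <- volume_grid(array(up, fine$dims), fine$spacing, fine$origin)
    }
    # augmented-score targets are the scores solved by the reconstruction,
    # frozen at the start of the dedicated encoder stage
    if (stg$augmentation == "motion_and_angle")
      solved_targets <- encode_projection(state$enc, projections$frames)
    if (verbose) message(sprintf(
      "stage %-4s: %d epochs @ %g mm [%s]", stg$stage, stg$epochs,
      stg$resolution, paste(stg$losses[[1]], collapse = "+")))
    state <- run_stage(state, stg, projections, gd, weights, batch_size,
                       label, image_subsample, solved_targets, history_acc)
    if (keep_checkpoints)
      checkpoints[[stg$stage]] <- list(inr_params = state$inr$params,
                                       encoder_params = state$enc$params,
                                       encoder_rstats = state$enc$rstats,
                                       basis_coef = state$basis$coef)
  }

  reference <- render_volume(state$inr, fine)
  solved_scores <- encode_projection(state$enc, projections$frames)
  basis_fields <- evaluate_basis(state$basis, fine)
  structure(list(
    inr = state$inr, encoder = state$enc, basis = state$basis,
    geometry = geom, grid = fine, grid_coarse = coarse,
    schedule = schedule, weights = weights, batch_size = batch_size,
    reference = reference, basis_fields = basis_fields,
    solved_scores = solved_scores, fdk = fdk,
    history = if (hptr > 0) do.call(rbind, history[seq_len(hptr)]) else
      history_row("", 0L, 0, c())[0, ],
    checkpoints = checkpoints,
    seed = seed, n_projections = np, call = cl), class = "rtcbct")
}

# ---------------------------------------------------------------------------
# optimizer

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(st, grad, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mhat <- st$m / (1 - beta1^st$t)
  vhat <- st$v / (1 - beta2^st$t)
  st$delta <- -lr * mhat / (sqrt(vhat) + eps)
  st
}

LOSS_KEYS <- c("image", "projection", "tv", "mbc", "zero_mean",
               "self_consistency", "augmentation")

history_row <- function(stage, epoch, total, terms) {
  row <- as.list(setNames(rep(NA_real_, length(LOSS_KEYS)), LOSS_KEYS))
  row[names(terms)] <- as.numeric(terms)
  cbind(data.frame(stage = stage, epoch = epoch, total = total),
        as.data.frame(row))
}

check_finite <- function(total, stage, epoch) {
  if (!is.finite(total))
    stop(sprintf("non-finite training loss at stage %s, epoch %d",
                 stage, epoch))
}

add_arr <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  a + b
}

# clip the joint gradient to global norm 10 and take one Adam step per
# trainable component
apply_updates <- function(state, stg, opt, grads) {
  sq <- 0
  for (g in grads) if (!is.null(g)) sq <- sq + sum(g^2)
  scale <- if (sq > 100) 10 / sqrt(sq) else 1
  if (!is.null(grads$inr) && stg$lr_inr > 0) {
    opt$inr <- adam_step(opt$inr, scale * grads$inr, stg$lr_inr)
    state$inr$params <- state$inr$params + opt$inr$delta
  }
  if (!is.null(grads$enc) && stg$lr_encoder > 0) {
    opt$enc <- adam_step(opt$enc, scale * as.numeric(grads$enc),
                         stg$lr_encoder)
    state$enc$params <- state$enc$params + opt$enc$delta
  }
  if (!is.null(grads$bas) && stg$lr_bspline > 0) {
    opt$bas <- adam_step(opt$bas, scale * grads$bas, stg$lr_bspline)
    state$basis$coef <- state$basis$coef + opt$bas$delta
  }
  attr(state, "opt") <- opt
  state
}

# ---------------------------------------------------------------------------
# one training stage

run_stage <- function(state, stg, projections, gd, weights, batch_size,
                      label, image_subsample, solved_targets, history_acc) {
  losses <- stg$losses[[1]]
  aug_mode <- stg$augmentation
  geom <- projections$geometry
  np <- n_frames(projections)
  n_pix <- geom$n_u * geom$n_v
  nvox <- prod(gd$dims)
  train_inr <- stg$lr_inr > 0
  train_enc <- stg$lr_encoder > 0
  train_bas <- stg$lr_bspline > 0

  opt <- list()
  if (train_inr) opt$inr <- adam_init(length(state$inr$params))
  if (train_enc) opt$enc <- adam_init(length(state$enc$params))
  if (train_bas) opt$bas <- adam_init(length(state$basis$coef))
  # learning-rate tail decay: constant for the first 70% of the stage,
  # then linear to zero (final-iterate smoothing that removes the SGD
  # noise floor from the hash tables without throttling convergence)
  anneal <- function(epoch) {
    if (stg$epochs <= 1) return(1)
    knee <- 0.7 * stg$epochs
    if (epoch <= knee) 1 else max(0, (stg$epochs - epoch) /
                                    (stg$epochs - knee))
  }

  need_motion_machinery <-
    any(c("projection", "self_consistency", "mbc") %in% losses) ||
    aug_mode != "off"
  # basis fields: recompute per step only while the B-spline trains
  E <- if (need_motion_machinery) evaluate_basis(state$basis, gd) else NULL
  # frozen-INR stages render the reference once
  iref_cache <- if (!train_inr && !("image" %in% losses))
    render_volume(state$inr, gd) else NULL

  perm <- sample.int(np)
  ptr <- 1L
  next_batch <- function() {
    if (ptr + batch_size - 1L > np) { perm <<- sample.int(np); ptr <<- 1L }
    b <- perm[ptr:(ptr + batch_size - 1L)]
    ptr <<- ptr + batch_size
    b
  }

  for (epoch in seq_len(stg$epochs)) {
    terms <- c()
    g_inr <- NULL; g_enc <- NULL; g_bas <- NULL

    if ("image" %in% losses) {
      idx <- if (nvox > image_subsample) sample.int(nvox, image_subsample)
             else NULL
      fw <- inr_forward(state$inr, gd, idx)
      lab <- as.numeric(label$data)
      if (!is.null(idx)) lab <- lab[idx]
      diffv <- fw$values - lab
      terms["image"] <- mean(diffv^2)
      g <- 2 * weights[["image"]] * diffv / length(diffv)
      g_inr <- inr_grad(state$inr, gd, g, idx = idx, cache = fw$cache)
    }

    if (aug_mode == "motion_and_angle") {
      # dedicated encoder stage: anatomy and motion model frozen; the
      # encoder learns to read motion- and angle-augmented DRRs
      bs <- next_batch()
      B <- length(bs)
      iref <- if (!is.null(iref_cache)) iref_cache else
        render_volume(state$inr, gd)
      tgt <- augment_scores(solved_targets[, bs, drop = FALSE])
      aug_ang <- runif(B, 0, 360)
      drrs <- array(0, c(geom$n_v, geom$n_u, B))
      for (b in seq_len(B)) {
        db <- compose_fast(tgt[, b], E, gd)
        wv <- warp_volume(iref, db)
        drrs[, , b] <- forward_project(wv, geom, aug_ang[b])
      }
      x_aug <- preprocess_frames(state$enc, drrs)
      aug_cache <- encoder_forward(state$enc, x_aug, B, train = TRUE)
      state$enc$rstats <- aug_cache$rstats
      pred <- aug_cache$scores
      terms["augmentation"] <- loss_augmentation(pred, tgt)
      gpred <- 2 * weights[["augmentation"]] * (pred - tgt) / (9 * B)
      bw <- encoder_backward(state$enc, x_aug, B, aug_cache, gpred,
                             train = TRUE)
      g_enc <- bw$gparams
    } else if ("projection" %in% losses || aug_mode != "off") {
      bs <- next_batch()
      B <- length(bs)
      iref_fw <- NULL
      iref <- if (!is.null(iref_cache)) iref_cache else {
        iref_fw <- inr_forward(state$inr, gd)
        volume_grid(array(iref_fw$values, gd$dims), gd$spacing, gd$origin)
      }
      meas <- projections$frames[, , bs, drop = FALSE]
      g_iref <- NULL      # accumulated dL/dIref voxel gradient
      g_E <- NULL         # accumulated dL/dE
      g_scores <- NULL    # accumulated dL/dscores (measured batch)

      motion_on <- !is.null(E) && (train_bas || train_enc ||
                                   any(state$basis$coef != 0))
      scores <- NULL; main_cache <- NULL; x_main <- NULL
      if (motion_on) {
        x_main <- preprocess_frames(state$enc, meas)
        main_cache <- encoder_forward(state$enc, x_main, B, train = train_enc)
        scores <- main_cache$scores
        if (train_enc) state$enc$rstats <- main_cache$rstats
      }

      # dynamic volumes of the batch
      vols <- vector("list", B); insides <- vector("list", B)
      dvfs <- vector("list", B)
      if (motion_on) {
        for (b in seq_len(B)) {
          dvfs[[b]] <- compose_fast(scores[, b], E, gd)
          wv <- warp_volume(iref, dvfs[[b]])
          vols[[b]] <- wv
          insides[[b]] <- attr(wv, "inside")
        }
      }

      g_vols <- vector("list", B)   # dL/d(dynamic volume b)
      if ("projection" %in% losses) {
        lp <- 0
        for (b in seq_len(B)) {
          src <- if (motion_on) vols[[b]] else iref
          drr <- forward_project(src, geom, geom$angles[bs[b]])
          diffp <- drr - meas[, , b]
          lp <- lp + mean(diffp^2)
          gdrr <- 2 * weights[["projection"]] * diffp / (B * n_pix)
          gb <- backproject_gradient(gdrr, gd, geom, geom$angles[bs[b]])
          g_vols[[b]] <- add_arr(g_vols[[b]], gb)
        }
        terms["projection"] <- lp / B
      }

      if ("self_consistency" %in% losses && motion_on) {
        lsc <- 0
        for (b in seq_len(B)) {
          dinv <- invert_raw(dvfs[[b]], 3)
          back <- warp_volume(vols[[b]], dinv)
          mask <- insides[[b]] & attr(back, "inside")
          nm <- sum(mask)
          if (nm == 0) next
          diffs <- (back$data - iref$data) * mask
          lsc <- lsc + sum(diffs^2) / nm
          gback <- 2 * weights[["self_consistency"]] * diffs / (nm * B)
          bwp <- cpp_warp_backward(vols[[b]]$data,
                                   dvf_flat(dinv), gback,
                                   gd$dims, gd$spacing, gd$origin,
                                   TRUE, FALSE)
          g_vols[[b]] <- add_arr(g_vols[[b]], array(bwp$gvol, gd$dims))
          g_iref <- add_arr(g_iref, -gback)
        }
        terms["self_consistency"] <- lsc / B
      }

      g_enc_aug <- NULL
      if (aug_mode == "angle_only") {
        # re-render DRRs of the solved dynamic volumes at random angles;
        # targets are the currently solved scores (no gradient through them)
        aug_ang <- runif(B, 0, 360)
        drrs <- array(0, c(geom$n_v, geom$n_u, B))
        for (b in seq_len(B)) {
          src <- if (motion_on) vols[[b]] else iref
          drrs[, , b] <- forward_project(src, geom, aug_ang[b])
        }
        x_aug <- preprocess_frames(state$enc, drrs)
        aug_cache <- encoder_forward(state$enc, x_aug, B, train = train_enc)
        if (train_enc) state$enc$rstats <- aug_cache$rstats
        pred <- aug_cache$scores
        tgt <- if (motion_on) scores else matrix(0, 9, B)
        terms["augmentation"] <- loss_augmentation(pred, tgt)
        gpred <- 2 * weights[["augmentation"]] * (pred - tgt) / (9 * B)
        need_gin <- train_inr || train_bas
        bw <- encoder_backward(state$enc, x_aug, B, aug_cache, gpred,
                               train = train_enc, need_ginput = need_gin)
        if (train_enc) g_enc_aug <- bw$gparams
        if (need_gin) {
          gdrr_aug <- preprocess_adjoint(state$enc, bw$ginput, geom$n_v,
                                         geom$n_u)
          for (b in seq_len(B)) {
            gb <- backproject_gradient(gdrr_aug[, , b], gd, geom, aug_ang[b])
            if (motion_on) g_vols[[b]] <- add_arr(g_vols[[b]], gb)
            else g_iref <- add_arr(g_iref, gb)
          }
        }
      }

      # backward through the warps: dynamic-volume gradients -> Iref, DVFs
      if (motion_on) {
        need_gdvf <- train_enc || train_bas
        Gk <- if (need_gdvf)
          lapply(1:3, function(k) matrix(0, nvox, B)) else NULL
        touched <- logical(B)
        for (b in seq_len(B)) {
          if (is.null(g_vols[[b]])) next
          bwp <- cpp_warp_backward(iref$data,
                                   dvf_flat(dvfs[[b]]),
                                   g_vols[[b]], gd$dims,
                                   gd$spacing, gd$origin, TRUE, need_gdvf)
          g_iref <- add_arr(g_iref, array(bwp$gvol, gd$dims))
          touched[b] <- TRUE
          if (need_gdvf) {
            gmat <- matrix(bwp$gdvf, ncol = 3)
            for (k in 1:3) Gk[[k]][, b] <- gmat[, k]
          }
        }
        if (need_gdvf && any(touched)) {
          for (k in 1:3) {
            j <- score_index(1:3, k)
            if (train_enc) {
              if (is.null(g_scores)) g_scores <- matrix(0, 9, B)
              g_scores[j, ] <- g_scores[j, ] +
                crossprod(E[, j, drop = FALSE], Gk[[k]])
            }
            if (train_bas) {
              if (is.null(g_E)) g_E <- matrix(0, nvox, 9)
              g_E[, j] <- g_E[, j] +
                Gk[[k]] %*% t(scores[j, , drop = FALSE])
            }
          }
        }
      } else {
        for (b in seq_len(B))
          if (!is.null(g_vols[[b]])) g_iref <- add_arr(g_iref, g_vols[[b]])
      }

      if ("tv" %in% losses) {
        tvr <- cpp_tv_loss_grad(iref$data, gd$dims, 1e-8, train_inr)
        terms["tv"] <- tvr$loss
        if (train_inr)
          g_iref <- add_arr(g_iref, weights[["tv"]] * array(tvr$grad, gd$dims))
      }
      if ("mbc" %in% losses) {
        terms["mbc"] <- loss_mbc_orthonormality(E)
        if (train_bas) {
          if (is.null(g_E)) g_E <- matrix(0, nvox, 9)
          g_E <- g_E + weights[["mbc"]] * mbc_gradient(E)
        }
      }
      if ("zero_mean" %in% losses && motion_on) {
        terms["zero_mean"] <- loss_zero_mean(scores)
        if (train_enc) {
          if (is.null(g_scores)) g_scores <- matrix(0, 9, B)
          g_scores <- g_scores +
            weights[["zero_mean"]] * zero_mean_gradient(scores)
        }
      }

      if (train_enc && !is.null(g_scores)) {
        bw_main <- encoder_backward(state$enc, x_main, B, main_cache,
                                    g_scores, train = TRUE)
        g_enc <- bw_main$gparams
      }
      g_enc <- add_arr(g_enc, g_enc_aug)
      if (train_inr && !is.null(g_iref))
        g_inr <- add_arr(g_inr,
                         inr_grad(state$inr, gd, as.numeric(g_iref),
                                  cache = if (!is.null(iref_fw))
                                    iref_fw$cache else NULL))
      if (train_bas && !is.null(g_E))
        g_bas <- basis_adjoint(state$basis, gd, g_E)
    }

    total <- sum(weights[names(terms)] * terms)
    check_finite(total, stg$stage, epoch)
    stg_t <- stg
    fac <- anneal(epoch)
    stg_t$lr_inr <- stg$lr_inr * fac
    stg_t$lr_encoder <- stg$lr_encoder * fac
    stg_t$lr_bspline <- stg$lr_bspline * fac
    state <- apply_updates(state, stg_t, opt,
                           list(inr = g_inr, enc = g_enc, bas = g_bas))
    opt <- attr(state, "opt")
    if (train_bas && !is.null(g_bas))
      E <- evaluate_basis(state$basis, gd)
    history_acc(history_row(stg$stage, epoch, total, terms))
  }
  state
}
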