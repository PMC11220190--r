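# Semi-supervised training loop.
#
# Each iteration pairs one random crop from a labeled scene with one from an
# unlabeled scene (batch size 2 = 1 + 1). An epoch is one shuffled pass over
# the unlabeled pool; the labeled pool cycles with reshuffling. The
# supervised loss (CE + Dice, primary decoder) is computed on the labeled
# crop, the multi-consistency loss on the unlabeled crop, and one
# momentum-SGD step is taken on lambda * L_s + beta(t) * L_u.

#' Training configuration
#'
#' @param epochs Number of epochs (default 100). An epoch is one pass over
#'   the unlabeled pool (or the labeled pool in supervised-only mode).
#' @param lr SGD learning rate (default 0.01).
#' @param momentum SGD momentum (default 0.9).
#' @param crop_size Side of the square training crops (default 64); must be
#'   divisible by `2^depth` of the model.
#' @param weights A [loss_weights].
#' @param seed Master seed; the data-order, feature-noise, and
#'   weight-initialization streams are derived from it.
#' @param deterministic Keep all randomness on the seeded streams so a rerun
#'   reproduces the loss trace bit-for-bit (default `TRUE`; there is no
#'   non-seeded randomness in this implementation, the flag is kept as an
#'   explicit contract).
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 100, lr = 0.01, momentum = 0.9,
                         crop_size = 64, weights = loss_weights(),
                         seed = 0L, deterministic = TRUE) {
  stopifnot(epochs >= 1, lr > 0, momentum >= 0, momentum < 1, crop_size >= 8)
  structure(list(epochs = epochs, lr = lr, momentum = momentum,
                 crop_size = crop_size, weights = weights,
                 seed = as.integer(seed), deterministic = deterministic),
            class = "train_config")
}

load_split_scenes <- function(manifest, split, with_masks) {
  rows <- manifest[manifest$split == split, ]
  purrr::map(seq_len(nrow(rows)), function(i) {
    list(scene_id = rows$scene_id[i],
         cube = read_cube(rows$cube[i]),
         mask = if (with_masks && rows$mask[i] != "") read_mask(rows$mask[i])
                else NULL)
  })
}

random_crop_origin <- function(dims, crop) {
  if (dims[1] < crop || dims[2] < crop) {
    stop("scene ", dims[1], "x", dims[2], " smaller than crop ", crop,
         call. = FALSE)
  }
  c(sample.int(dims[1] - crop + 1L, 1L), sample.int(dims[2] - crop + 1L, 1L))
}

#' Build the batch schedule for one training run
#'
#' Returns the sequence of (labeled scene, unlabeled scene, crop origins)
#' for `epochs` epochs. Every unlabeled scene appears exactly once per epoch
#' in shuffled order; labeled scenes cycle with reshuffling when exhausted,
#' so over one epoch each labeled scene appears `floor` or `ceiling` of
#' `N/M` times. With no unlabeled scenes the schedule runs over the labeled
#' pool alone (supervised-only mode).
#'
#' @param n_labeled,n_unlabeled Pool sizes (labeled must be >= 1).
#' @param epochs Number of epochs.
#' @param stream `rng_stream` driving the shuffles.
#' @return Tibble with columns `t`, `epoch`, `labeled`, `unlabeled`
#'   (unlabeled is `NA` in supervised-only mode).
#' @export
make_batches <- function(n_labeled, n_unlabeled, epochs, stream) {
  if (n_labeled < 1) stop("no labeled scenes", call. = FALSE)
  iters <- max(1L, if (n_unlabeled > 0) n_unlabeled else n_labeled)
  with_stream(stream, {
    lab_pool <- integer(0)
    rows <- vector("list", epochs * iters)
    t <- 0L
    for (ep in seq_len(epochs)) {
      unl <- if (n_unlabeled > 0) sample.int(n_unlabeled) else rep(NA_integer_, iters)
      for (k in seq_len(iters)) {
        if (!length(lab_pool)) lab_pool <- sample.int(n_labeled)
        t <- t + 1L
        rows[[t]] <- tibble::tibble(t = t, epoch = ep,
                                    labeled = lab_pool[1], unlabeled = unl[k])
        lab_pool <- lab_pool[-1]
      }
    }
    dplyr::bind_rows(rows)
  })
}

crop3 <- function(a, org, crop) {
  a[org[1]:(org[1] + crop - 1), org[2]:(org[2] + crop - 1), , drop = FALSE]
}
crop2 <- function(m, org, crop) {
  m[org[1]:(org[1] + crop - 1), org[2]:(org[2] + crop - 1), drop = FALSE]
}

# dLoss/dlogits for CE (pixel mean) + soft Dice against a hard or soft
# target, chained through the per-pixel softmax.
ce_dice_glogits <- function(probs, target) {
  d <- dim(probs)
  y <- target_to_onehot(target, d)
  npix <- d[1] * d[2]
  g_ce <- (probs - y) / npix          # CE through softmax
  # soft-Dice gradient wrt probabilities
  g_dice_p <- array(0, d)
  for (c in 1:2) {
    p <- probs[, , c]; t <- y[, , c]
    num <- 2 * sum(p * t) + DICE_EPS
    den <- sum(p) + sum(t) + DICE_EPS
    g_dice_p[, , c] <- -0.5 * (2 * t * den - num) / den^2
  }
  # chain through softmax: dz_c = p_c * (g_c - sum_k g_k p_k)
  gp_dot <- g_dice_p[, , 1] * probs[, , 1] + g_dice_p[, , 2] * probs[, , 2]
  g_dice <- array(0, d)
  for (c in 1:2) {
    g_dice[, , c] <- probs[, , c] * (g_dice_p[, , c] - gp_dot)
  }
  g_ce + g_dice
}

#' One semi-supervised training step
#'
#' Forward the labeled crop through the encoder and primary decoder for the
#' supervised loss; forward the unlabeled crop through all decoders
#' (auxiliary bottleneck inputs perturbed), form Soft-Hard pseudo-labels,
#' and apply the multi-consistency loss; combine with the warm-up schedule
#' and take one momentum-SGD step. Pseudo-labels are plain values — no
#' gradient flows through the target side of any pair.
#'
#' @param model An `mcl_net`.
#' @param labeled List `list(x, mask)`: PCA-reduced crop and its mask.
#' @param unlabeled PCA-reduced crop array, or `NULL` for a supervised-only
#'   step.
#' @param weights A [loss_weights].
#' @param opt Optimizer state `list(vel, lr, momentum)`.
#' @param t,t_max Iteration counters.
#' @param noise_stream `rng_stream` for the feature noise.
#' @return List with updated `model`, `opt`, and the loss components
#'   `L_s`, `L_u`, `beta`, `L`.
#' @export
train_step <- function(model, labeled, unlabeled, weights, opt, t, t_max,
                       noise_stream) {
  cfg <- model$cfg
  beta <- (weights$beta_amplitude / 0.001) * warmup_beta(t, t_max)

  # supervised path: primary decoder only
  fw_l <- forward_mcl(model, labeled$x, training = FALSE)
  L_s <- supervised_loss(fw_l$probs[[1]], labeled$mask)
  gl <- ce_dice_glogits(fw_l$probs[[1]], labeled$mask)
  grads <- backward_mcl(model, fw_l, list(gl * weights$lambda))

  # unsupervised path: all decoders, pairwise consistency
  L_u <- NULL
  unsup_inputs <- list()
  if (!is.null(unlabeled) && cfg$n_decoders > 1) unsup_inputs <- list(unlabeled)
  if (weights$consistency_on_labeled && cfg$n_decoders > 1) {
    unsup_inputs <- c(unsup_inputs, list(labeled$x))
  }
  for (xu in unsup_inputs) {
    fw_u <- forward_mcl(model, xu, training = TRUE,
                        noise_stream = noise_stream)
    pseudo <- soft_hard_labels(fw_u$probs, weights$T)
    L_u_k <- multi_consistency_loss(fw_u$probs, pseudo,
                                    weights$consistency_mode)
    L_u <- (L_u %||% 0) + L_u_k
    glu <- vector("list", cfg$n_decoders)
    for (i in seq_len(cfg$n_decoders)) {
      g <- NULL
      for (j in seq_len(cfg$n_decoders)) {
        if (i == j) next
        target <- if (weights$consistency_mode == "hard") pseudo[[j]]$hard
                  else array(c(1 - pseudo[[j]]$soft, pseudo[[j]]$soft),
                             dim(fw_u$probs[[i]]))
        gij <- ce_dice_glogits(fw_u$probs[[i]], target)
        g <- if (is.null(g)) gij else g + gij
      }
      glu[[i]] <- if (is.null(g)) NULL else g * beta
    }
    grads <- tree_add(grads, backward_mcl(model, fw_u, glu))
  }

  L <- weights$lambda * L_s + beta * (L_u %||% 0)
  if (!is.finite(L)) {
    stop("non-finite loss at t = ", t, " (L_s = ", L_s, ", L_u = ",
         L_u %||% NA, ")", call. = FALSE)
  }
  st <- sgd_step(model$params, grads, opt$vel, opt$lr, opt$momentum)
  model$params <- st$params
  opt$vel <- st$vel
  list(model = model, opt = opt, L_s = L_s, L_u = L_u %||% NA_real_,
       beta = beta, L = L)
}

#' Train the semi-supervised segmentation model
#'
#' @param manifest Manifest tibble from [load_manifest()] or
#'   [generate_dataset()].
#' @param model_cfg A [mcl_config].
#' @param tc A [train_config].
#' @param pca Optional fitted `pca_bands`; when `NULL`, PCA is fitted on the
#'   pooled labeled + unlabeled training cubes with `k = in_channels`.
#' @param out_dir Optional run directory; when given, the final and best
#'   checkpoints and the training-log CSV are written there.
#' @param track_best Evaluate training-Dice on the labeled scenes at the end
#'   of each epoch and keep the best checkpoint (default `TRUE`).
#' @param quiet Suppress progress messages.
#' @return An `mcl_fit`: list with the trained `model`, `best_model`, `pca`,
#'   `log` (tibble `t, epoch, L_s, L_u, beta, L`), `t_max`, and the configs.
#' @export
train_mcl <- function(manifest, model_cfg = mcl_config(),
                      tc = train_config(), pca = NULL, out_dir = NULL,
                      track_best = TRUE, quiet = FALSE) {
  stopifnot(inherits(model_cfg, "mcl_config"), inherits(tc, "train_config"))
  if (tc$crop_size %% 2^model_cfg$depth != 0) {
    stop("crop_size ", tc$crop_size, " not divisible by 2^depth = ",
         2^model_cfg$depth, call. = FALSE)
  }
  labeled <- load_split_scenes(manifest, "labeled", with_masks = TRUE)
  unlabeled <- load_split_scenes(manifest, "unlabeled", with_masks = FALSE)
  if (!length(labeled)) stop("no labeled scenes in manifest", call. = FALSE)
  supervised_only <- length(unlabeled) == 0 || model_cfg$n_decoders == 1
  if (!quiet && supervised_only) {
    message("supervised-only mode (no unlabeled scenes or n_decoders = 1)")
  }
  if (is.null(pca)) {
    pca <- fit_pca(c(purrr::map(labeled, "cube"),
                     purrr::map(unlabeled, "cube")),
                   k = model_cfg$in_channels, seed = tc$seed)
  }
  lab_x <- purrr::map(labeled, function(s) apply_pca(pca, s$cube))
  unl_x <- purrr::map(unlabeled, function(s) apply_pca(pca, s$cube))

  data_stream <- rng_stream(mix_seed(tc$seed, 1L))
  noise_stream <- rng_stream(mix_seed(tc$seed, 2L))
  model <- build_model(mcl_config(
    in_channels = model_cfg$in_channels, n_classes = model_cfg$n_classes,
    n_decoders = model_cfg$n_decoders, depth = model_cfg$depth,
    base_width = model_cfg$base_width, noise = model_cfg$noise,
    noise_mode = model_cfg$noise_mode, seed = mix_seed(tc$seed, 3L)))

  schedule <- make_batches(length(labeled),
                           if (supervised_only) 0L else length(unlabeled),
                           tc$epochs, data_stream)
  t_max <- nrow(schedule)
  opt <- list(vel = zero_like(model$params), lr = tc$lr,
              momentum = tc$momentum)
  log_rows <- vector("list", t_max)
  best <- list(dice = -Inf, model = NULL)
  crop <- tc$crop_size
  iters_per_epoch <- t_max / tc$epochs

  for (k in seq_len(t_max)) {
    b <- schedule[k, ]
    li <- b$labeled
    origins <- with_stream(data_stream, {
      o1 <- random_crop_origin(dim(lab_x[[li]]), crop)
      o2 <- if (!is.na(b$unlabeled)) {
        random_crop_origin(dim(unl_x[[b$unlabeled]]), crop)
      } else NULL
      list(o1 = o1, o2 = o2)
    })
    lab_crop <- list(x = crop3(lab_x[[li]], origins$o1, crop),
                     mask = crop2(unclass(labeled[[li]]$mask), origins$o1, crop))
    unl_crop <- if (!supervised_only && !is.na(b$unlabeled)) {
      crop3(unl_x[[b$unlabeled]], origins$o2, crop)
    } else NULL
    st <- train_step(model, lab_crop, unl_crop, tc$weights, opt,
                     t = b$t, t_max = t_max, noise_stream = noise_stream)
    model <- st$model
    opt <- st$opt
    log_rows[[k]] <- tibble::tibble(t = b$t, epoch = b$epoch, L_s = st$L_s,
                                    L_u = st$L_u, beta = st$beta, L = st$L)
    if (track_best && (k %% iters_per_epoch == 0)) {
      dice <- training_dice(model, lab_x, labeled)
      if (dice > best$dice) best <- list(dice = dice, model = model)
      if (!quiet && b$epoch %% 10 == 0) {
        message(sprintf("epoch %d  L = %.4f  labeled-Dice = %.4f",
                        b$epoch, st$L, dice))
      }
    }
  }
  log <- dplyr::bind_rows(log_rows)
  fit <- structure(list(model = model,
                        best_model = best$model %||% model,
                        best_dice = if (is.finite(best$dice)) best$dice else NA_real_,
                        pca = pca, log = log, t_max = t_max,
                        model_cfg = model_cfg, train_cfg = tc),
                   class = "mcl_fit")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_checkpoint(fit, file.path(out_dir, "final.ckpt.rds"))
    utils::write.csv(log, file.path(out_dir, "training_log.csv"),
                     row.names = FALSE)
  }
  fit
}

# mean hard Dice of the primary decoder over the labeled scenes
training_dice <- function(model, lab_x, labeled) {
  dices <- vapply(seq_along(lab_x), function(i) {
    pred <- predict_reduced(model, lab_x[[i]])
    cc <- confusion_counts(pred$mask, labeled[[i]]$mask)
    suppressMessages(dice_coefficient(cc))
  }, numeric(1))
  mean(dices)
}

# inference on an already PCA-reduced array that fits the network directly
predict_reduced <- function(model, x) {
  fw <- forward_mcl(model, x, training = FALSE)
  prob <- fw$probs[[1]][, , 2]
  list(mask = label_mask(matrix(as.integer(prob > 0.5), nrow(prob))),
       prob = prob)
}

#' Predict a full scene by tiled primary-decoder inference
#'
#' The scene is covered with overlapping square tiles, per-pixel tumor
#' probabilities are averaged over all covering tiles, and the averaged map
#' is thresholded at 0.5 (ties resolve to normal).
#'
#' @param model An `mcl_net` or `mcl_fit`.
#' @param cube A [hyper_cube], or an already PCA-reduced H x W x k array.
#' @param pca `pca_bands` used to reduce `cube`; required when `cube` still
#'   carries full bands (taken from the fit if available).
#' @param tile Tile side; defaults to the training crop size if called on a
#'   fit, else 64. Must be divisible by `2^depth`.
#' @param overlap Fractional tile overlap in `[0, 1)` (default 0.5).
#' @return List with `mask` ([label_mask]) and `prob` (H x W tumor
#'   probabilities).
#' @export
predict_scene <- function(model, cube, pca = NULL, tile = NULL,
                          overlap = 0.5) {
  if (inherits(model, "mcl_fit")) {
    pca <- pca %||% model$pca
    tile <- tile %||% model$train_cfg$crop_size
    model <- model$best_model
  }
  x <- if (inherits(cube, "hyper_cube")) {
    if (dim(cube$data)[3] == model$cfg$in_channels && is.null(pca)) cube$data
    else apply_pca(pca, cube)
  } else cube
  d <- dim(x)
  tile <- tile %||% 64L
  if (tile %% 2^model$cfg$depth != 0) {
    stop("tile size not divisible by 2^depth", call. = FALSE)
  }
  if (d[1] <= tile && d[2] <= tile) {
    if (d[1] == tile && d[2] == tile) return(predict_reduced(model, x))
    stop("scene ", d[1], "x", d[2], " smaller than tile ", tile, call. = FALSE)
  }
  step <- max(1L, as.integer(round(tile * (1 - overlap))))
  starts <- function(n) {
    s <- unique(c(seq(1L, n - tile + 1L, by = step), n - tile + 1L))
    s
  }
  acc <- matrix(0, d[1], d[2])
  cnt <- matrix(0, d[1], d[2])
  for (i0 in starts(d[1])) {
    for (j0 in starts(d[2])) {
      sub <- x[i0:(i0 + tile - 1), j0:(j0 + tile - 1), , drop = FALSE]
      fw <- forward_mcl(model, sub, training = FALSE)
      acc[i0:(i0 + tile - 1), j0:(j0 + tile - 1)] <-
        acc[i0:(i0 + tile - 1), j0:(j0 + tile - 1)] + fw$probs[[1]][, , 2]
      cnt[i0:(i0 + tile - 1), j0:(j0 + tile - 1)] <-
        cnt[i0:(i0 + tile - 1), j0:(j0 + tile - 1)] + 1
    }
  }
  prob <- acc / cnt
  list(mask = label_mask(matrix(as.integer(prob > 0.5), d[1])), prob = prob)
}

#' Save / load a training checkpoint
#'
#' @param fit An `mcl_fit` (or `mcl_net`).
#' @param path RDS file path.
#' @return `write_checkpoint` returns the path invisibly; `read_checkpoint`
#'   the restored object.
#' @export
write_checkpoint <- function(fit, path) {
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) readRDS(path)
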