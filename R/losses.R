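# Training objectives.
#
# Supervised loss = cross-entropy + soft Dice on the primary decoder's
# probability map. Pseudo-labels for unlabeled data come from the Soft-Hard
# process: temperature sharpening of the tumor probability followed by
# argmax. The multi-consistency loss sums CE + Dice over all ordered decoder
# pairs (i, j), i != j, treating decoder j's hard pseudo-label as the target
# for decoder i. The total objective is lambda * L_s + beta(t) * L_u with a
# Gaussian warm-up beta.

CE_CLIP <- 1e-7
DICE_EPS <- 1e-5

# target as H x W x 2 one-hot / soft array
target_to_onehot <- function(target, dims) {
  if (length(dim(target)) == 3L) return(target)
  td <- dim(target)
  if (is.null(td)) td <- c(length(target), 1L)
  if (length(td) != 2L || td[1] != dims[1] || td[2] != dims[2]) {
    stop("probs/target shape mismatch", call. = FALSE)
  }
  y1 <- matrix(as.numeric(target), dims[1], dims[2])
  array(c(1 - y1, y1), c(dims[1], dims[2], 2))
}

#' Pixel-mean cross-entropy loss
#'
#' Mean over pixels of `-log p(target class)`, with probabilities clipped to
#' `[1e-7, 1 - 1e-7]`. `target` may be a binary class map or an H x W x 2
#' soft target.
#'
#' @param probs H x W x 2 array of class probabilities (must sum to 1 per
#'   pixel).
#' @param target H x W class map in \{0, 1\}, or an H x W x 2 soft target.
#' @return Non-negative scalar.
#' @export
cross_entropy_loss <- function(probs, target) {
  d <- dim(probs)
  y <- target_to_onehot(target, d)
  if (!all(dim(y) == d)) stop("probs/target shape mismatch", call. = FALSE)
  p <- pmin(pmax(probs, CE_CLIP), 1 - CE_CLIP)
  -sum(y * log(p)) / (d[1] * d[2])
}

#' Soft Dice loss
#'
#' For each class c: `1 - (2 * sum(p_c * y_c) + eps) / (sum(p_c) + sum(y_c)
#' + eps)` with `eps = 1e-5`, averaged over the two classes. Probabilities
#' enter unthresholded (soft Dice).
#'
#' @inheritParams cross_entropy_loss
#' @return Scalar in `[0, 1]` (up to the eps smoothing).
#' @export
dice_loss <- function(probs, target) {
  d <- dim(probs)
  y <- target_to_onehot(target, d)
  if (!all(dim(y) == d)) stop("probs/target shape mismatch", call. = FALSE)
  per_class <- vapply(1:2, function(c) {
    p <- probs[, , c]; t <- y[, , c]
    1 - (2 * sum(p * t) + DICE_EPS) / (sum(p) + sum(t) + DICE_EPS)
  }, numeric(1))
  mean(per_class)
}

#' Supervised loss on the primary decoder
#'
#' `L_s = L_CE + L_Dice` between the primary decoder's probability map and
#' the ground-truth mask. Auxiliary decoder outputs never enter the
#' supervised term.
#'
#' @param primary_probs H x W x 2 probability map from the primary decoder.
#' @param mask Ground-truth [label_mask] (H x W in \{0, 1\}).
#' @return Non-negative scalar.
#' @export
supervised_loss <- function(primary_probs, mask) {
  if (is.null(mask)) {
    stop("supervised_loss requires a labeled sample", call. = FALSE)
  }
  cross_entropy_loss(primary_probs, mask) + dice_loss(primary_probs, mask)
}

#' Temperature sharpening of a tumor-probability map
#'
#' `P_S = p^(1/T) / (p^(1/T) + (1 - p)^(1/T))`. T = 1 is the identity;
#' T < 1 pushes probabilities toward 0/1 (entropy minimization); p = 0.5 is
#' a fixed point for every T.
#'
#' @param p Array/vector of tumor probabilities in `[0, 1]`.
#' @param T Sharpening temperature, > 0 (default 0.5).
#' @return Soft pseudo-label of the same shape, values in `[0, 1]`.
#' @export
sharpen <- function(p, T = 0.5) {
  if (T <= 0) stop("temperature T must be > 0", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  a <- p^(1 / T)
  b <- (1 - p)^(1 / T)
  out <- a / (a + b)
  # p in {0,1} can yield 0/0 for tiny T; the limit is p itself
  deg <- !is.finite(out)
  if (any(deg)) out[deg] <- p[deg]
  out
}

#' Hard pseudo-label from a soft pseudo-label
#'
#' Argmax over the two classes: 1 where `P_S > 0.5`, else 0. The tie at
#' exactly 0.5 resolves to class 0 (normal), deterministically. Pseudo-labels
#' are plain values: no training gradient flows through them.
#'
#' @param P_S Soft pseudo-label array in `[0, 1]`.
#' @return Integer array of the same shape in \{0, 1\}.
#' @export
hard_label <- function(P_S) {
  h <- as.integer(P_S > 0.5)
  if (!is.null(dim(P_S))) dim(h) <- dim(P_S)
  h
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Soft-Hard pseudo-labels for a set of decoder outputs
#'
#' @param probs_list List of H x W x 2 probability maps, one per decoder.
#' @param T Sharpening temperature.
#' @return List of `list(soft, hard, decoder)` pseudo-label pairs.
#' @export
soft_hard_labels <- function(probs_list, T = 0.5) {
  lapply(seq_along(probs_list), function(i) {
    d <- dim(probs_list[[i]])
    P_S <- sharpen(matrix(probs_list[[i]][, , 2], d[1], d[2]), T)
    list(soft = P_S, hard = hard_label(P_S), decoder = i)
  })
}

#' Multi-consistency loss across decoders
#'
#' Sum over all ordered decoder pairs (i, j), i != j, of
#' `CE(map_i, target_j) + Dice(map_i, target_j)`. In `"hard"` mode (the
#' default) the target is decoder j's hard pseudo-label; in `"soft"` mode it
#' is the two-channel soft label `(1 - P_S_j, P_S_j)`. The sum is not
#' averaged over pairs; the warm-up weight absorbs the scale. With a single
#' decoder the pair sum is empty and the loss is 0.
#'
#' @param maps List of n H x W x 2 probability maps.
#' @param pseudo List of n pseudo-label sets from [soft_hard_labels()].
#' @param mode `"hard"` or `"soft"`.
#' @return Non-negative scalar.
#' @export
multi_consistency_loss <- function(maps, pseudo, mode = c("hard", "soft")) {
  mode <- match.arg(mode)
  n <- length(maps)
  if (n == 0) stop("no probability maps supplied", call. = FALSE)
  if (length(pseudo) != n) {
    stop("need one pseudo-label set per decoder", call. = FALSE)
  }
  if (n == 1) return(0)
  total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      target <- if (mode == "hard") pseudo[[j]]$hard else {
        d <- dim(maps[[i]])
        array(c(1 - pseudo[[j]]$soft, pseudo[[j]]$soft), d)
      }
      total <- total + cross_entropy_loss(maps[[i]], target) +
        dice_loss(maps[[i]], target)
    }
  }
  total
}

#' Gaussian warm-up weight for the unsupervised loss
#'
#' `beta(t) = 0.001 * exp(-5 * (1 - t / t_max)^2)`: near zero early in
#' training, when pseudo-labels are unreliable, rising monotonically to
#' 0.001 at the final iteration.
#'
#' @param t Current iteration, `0 <= t <= t_max`.
#' @param t_max Maximum iteration count, > 0.
#' @return The weight beta.
#' @export
warmup_beta <- function(t, t_max) {
  if (t_max <= 0) stop("t_max must be > 0", call. = FALSE)
  if (any(t < 0) || any(t > t_max)) {
    stop("t must lie in [0, t_max]", call. = FALSE)
  }
  0.001 * exp(-5 * (1 - t / t_max)^2)
}

#' Loss weights and schedule parameters
#'
#' @param lambda Supervised-loss weight (default 0.5).
#' @param T Sharpening temperature (default 0.5).
#' @param beta_amplitude Plateau value of the warm-up weight (default 0.001).
#' @param consistency_mode `"hard"` or `"soft"` pseudo-label targets.
#' @param consistency_on_labeled Also apply the consistency loss to labeled
#'   inputs (ablation switch; default `FALSE` — the unsupervised term is
#'   computed on the unlabeled batch only).
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(lambda = 0.5, T = 0.5, beta_amplitude = 0.001,
                         consistency_mode = c("hard", "soft"),
                         consistency_on_labeled = FALSE) {
  stopifnot(lambda >= 0, T > 0, beta_amplitude >= 0)
  structure(list(lambda = lambda, T = T, beta_amplitude = beta_amplitude,
                 consistency_mode = match.arg(consistency_mode),
                 consistency_on_labeled = consistency_on_labeled),
            class = "loss_weights")
}

#' Total training loss
#'
#' `L = lambda * L_s + beta(t, t_max) * L_u`. When the batch has no
#' unlabeled sample, `L_u` is absent and the total reduces to
#' `lambda * L_s`.
#'
#' @param L_s Supervised loss value.
#' @param L_u Unsupervised (multi-consistency) loss value, or `NULL`.
#' @param weights A [loss_weights].
#' @param t,t_max Iteration counters for the warm-up schedule.
#' @return Scalar total loss.
#' @export
total_loss <- function(L_s, L_u, weights, t, t_max) {
  beta <- (weights$beta_amplitude / 0.001) * warmup_beta(t, t_max)
  L_u <- L_u %||% 0
  stopifnot(is.finite(L_s), is.finite(L_u))
  weights$lambda * L_s + beta * L_u
}
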