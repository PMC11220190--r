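# The multi-consistency segmentation network: one shared U-Net encoder,
# n independent U-Net decoders, and Gaussian feature-noise perturbation of
# the bottleneck representation feeding the auxiliary decoders. Decoder 1
# is the primary decoder: it alone is used at inference, its input is never
# perturbed, and the supervised loss is computed on its output only.

#' Model configuration
#'
#' @param in_channels Input channels after PCA band reduction (default 6).
#' @param n_classes Number of classes; fixed at 2 (normal, tumor).
#' @param n_decoders Number of decoders n (default 3). `n_decoders = 1` is a
#'   plain supervised U-Net: no auxiliary decoders, no feature noise, and no
#'   consistency objective.
#' @param depth Number of encoder down-sampling steps (default 4); input
#'   spatial dims must be divisible by `2^depth`.
#' @param base_width Channel width of the first encoder level (default 16),
#'   doubling per level.
#' @param noise List of `n_decoders - 1` auxiliary-decoder noise specs, each
#'   `list(mean, sd)`; defaults to `list(list(1, 1.2), list(1, 1.5))` for
#'   n = 3.
#' @param noise_mode `"additive"` (bottleneck + eps, the default reading of
#'   mean-1 Gaussian feature noise) or `"multiplicative"` (bottleneck * eps).
#' @param seed Weight-initialization seed.
#' @return A `mcl_config` list.
#' @export
mcl_config <- function(in_channels = 6, n_classes = 2, n_decoders = 3,
                       depth = 4, base_width = 16,
                       noise = NULL,
                       noise_mode = c("additive", "multiplicative"),
                       seed = 0L) {
  if (n_decoders < 1) stop("n_decoders must be >= 1", call. = FALSE)
  if (n_classes != 2) stop("only 2-class segmentation is supported", call. = FALSE)
  noise_mode <- match.arg(noise_mode)
  if (is.null(noise)) {
    default_noise <- list(list(mean = 1, sd = 1.2), list(mean = 1, sd = 1.5))
    noise <- if (n_decoders <= 1) list() else
      lapply(seq_len(n_decoders - 1), function(i) {
        default_noise[[(i - 1) %% 2 + 1]]
      })
  }
  noise <- lapply(noise, function(sp) {
    sp <- setNames(as.list(unlist(sp)), c("mean", "sd"))
    if (sp$sd < 0) stop("noise sd must be >= 0", call. = FALSE)
    sp
  })
  if (length(noise) != n_decoders - 1) {
    stop("need exactly n_decoders - 1 = ", n_decoders - 1,
         " noise specs, got ", length(noise), call. = FALSE)
  }
  structure(list(in_channels = in_channels, n_classes = n_classes,
                 n_decoders = n_decoders, depth = depth,
                 base_width = base_width, noise = noise,
                 noise_mode = noise_mode, seed = as.integer(seed)),
            class = "mcl_config")
}

decoder_params <- function(cfg, widths) {
  depth <- cfg$depth
  levels <- vector("list", depth)
  for (l in seq_len(depth)) {
    w_in <- widths[l + 1]  # width arriving from below
    w <- widths[l]
    levels[[l]] <- list(up = init_conv(w_in, w, 3L),
                        c1 = init_conv(2 * w, w, 3L),
                        c2 = init_conv(w, w, 3L))
  }
  list(levels = levels, out = init_conv(widths[1], cfg$n_classes, 1L))
}

#' Build the segmentation network
#'
#' Constructs the shared encoder and `n_decoders` independently initialized
#' decoders. Initialization is drawn from a seeded stream, so two builds
#' from the same config are bit-identical.
#'
#' @param cfg A [mcl_config].
#' @return An object of class `mcl_net` holding the config and parameters.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "mcl_config"))
  widths <- cfg$base_width * 2^(0:cfg$depth)  # level widths, then bottleneck
  with_stream(rng_stream(mix_seed(cfg$seed, 7L)), {
    enc_levels <- vector("list", cfg$depth)
    cin <- cfg$in_channels
    for (l in seq_len(cfg$depth)) {
      enc_levels[[l]] <- list(c1 = init_conv(cin, widths[l], 3L),
                              c2 = init_conv(widths[l], widths[l], 3L))
      cin <- widths[l]
    }
    bottleneck <- list(c1 = init_conv(widths[cfg$depth], widths[cfg$depth + 1], 3L),
                       c2 = init_conv(widths[cfg$depth + 1], widths[cfg$depth + 1], 3L))
    decoders <- lapply(seq_len(cfg$n_decoders), function(d) {
      decoder_params(cfg, widths)
    })
    structure(list(cfg = cfg, widths = widths,
                   params = list(enc = list(levels = enc_levels,
                                            bottleneck = bottleneck),
                                 dec = decoders)),
              class = "mcl_net")
  })
}

#' @export
print.mcl_net <- function(x, ...) {
  cat(sprintf(paste0("<mcl_net> %d decoder(s), depth %d, base width %d, ",
                     "%d input channels, %s parameters\n"),
              x$cfg$n_decoders, x$cfg$depth, x$cfg$base_width,
              x$cfg$in_channels, format(n_params(x$params), big.mark = ",")))
  invisible(x)
}

#' Count model parameters
#'
#' @param model An `mcl_net`, or a parameter subtree.
#' @return Total number of scalar weights and biases.
#' @export
count_params <- function(model) {
  if (inherits(model, "mcl_net")) n_params(model$params) else n_params(model)
}

#' Perturb a bottleneck feature tensor
#'
#' Applies elementwise Gaussian feature noise to the bottleneck activation
#' feeding an auxiliary decoder. In additive mode the result is
#' `FA + eps`, in multiplicative mode `FA * eps`, with
#' `eps ~ Normal(mean, sd^2)` drawn elementwise. Noise is only used during
#' training; inference runs the primary decoder on the unperturbed features.
#'
#' @param FA Bottleneck activation array.
#' @param mean,sd Noise distribution parameters (`sd = 0` gives the
#'   deterministic shift `FA + mean`, or `FA * mean`).
#' @param stream An `rng_stream` supplying the draw; `NULL` uses the current
#'   RNG state.
#' @param mode `"additive"` or `"multiplicative"`.
#' @return A list with `FA` (perturbed tensor) and `eps` (the noise drawn,
#'   needed to backpropagate through multiplicative noise).
#' @export
perturb_features <- function(FA, mean, sd, stream = NULL,
                             mode = c("additive", "multiplicative")) {
  mode <- match.arg(mode)
  stopifnot(sd >= 0)
  draw <- function() array(rnorm(length(FA), mean = mean, sd = sd), dim(FA))
  eps <- if (is.null(stream)) draw() else with_stream(stream, draw())
  out <- if (mode == "additive") FA + eps else FA * eps
  list(FA = out, eps = eps)
}

# ---- forward / backward ----------------------------------------------------

encoder_fw <- function(params, x, depth) {
  skips <- vector("list", depth)
  dc_caches <- vector("list", depth)
  pool_idx <- vector("list", depth)
  pre_dims <- vector("list", depth)
  h <- x
  for (l in seq_len(depth)) {
    dc <- dconv_fw(h, params$levels[[l]]$c1, params$levels[[l]]$c2)
    skips[[l]] <- dc$out
    dc_caches[[l]] <- dc$cache
    pre_dims[[l]] <- dim(dc$out)
    mp <- cpp_maxpool2_fw(dc$out)
    pool_idx[[l]] <- mp$idx
    h <- mp$y
  }
  bott <- dconv_fw(h, params$bottleneck$c1, params$bottleneck$c2)
  list(FA = bott$out, skips = skips,
       cache = list(dc = dc_caches, pool_idx = pool_idx,
                    pre_dims = pre_dims, bott = bott$cache))
}

encoder_bw <- function(params, gFA, gskips, cache, depth) {
  bb <- dconv_bw(gFA, cache$bott, params$bottleneck$c1, params$bottleneck$c2)
  g_levels <- vector("list", depth)
  gh <- bb$gx
  for (l in rev(seq_len(depth))) {
    d <- cache$pre_dims[[l]]
    gs <- cpp_maxpool2_bw(gh, cache$pool_idx[[l]], d[1], d[2])
    if (!is.null(gskips[[l]])) gs <- gs + gskips[[l]]
    lb <- dconv_bw(gs, cache$dc[[l]],
                   params$levels[[l]]$c1, params$levels[[l]]$c2)
    g_levels[[l]] <- list(c1 = lb$g1, c2 = lb$g2)
    gh <- lb$gx
  }
  list(gx = gh,
       grads = list(levels = g_levels,
                    bottleneck = list(c1 = bb$g1, c2 = bb$g2)))
}

decoder_fw <- function(dparams, FA, skips, depth, widths) {
  h <- FA
  lv_cache <- vector("list", depth)
  for (l in rev(seq_len(depth))) {
    in_dim <- dim(h)
    u <- cpp_upsample2_fw(h)
    a <- conv_fw(u, dparams$levels[[l]]$up)
    r <- relu(a)
    w <- widths[l]
    xcat <- array(c(skips[[l]], r), c(dim(r)[1], dim(r)[2], 2 * w))
    dc <- dconv_fw(xcat, dparams$levels[[l]]$c1, dparams$levels[[l]]$c2)
    lv_cache[[l]] <- list(in_dim = in_dim, u = u, m = a > 0, dc = dc$cache,
                          w = w)
    h <- dc$out
  }
  logits <- conv_fw(h, dparams$out)
  list(logits = logits, probs = softmax2(logits),
       cache = list(levels = lv_cache, h_final = h))
}

decoder_bw <- function(dparams, glogits, cache, depth) {
  ob <- cpp_conv2d_bw(cache$h_final, dparams$out$W, glogits, dparams$out$k)
  gh <- ob$gx
  gskips <- vector("list", depth)
  g_levels <- vector("list", depth)
  for (l in seq_len(depth)) {  # shallow to deep
    cl <- cache$levels[[l]]
    db <- dconv_bw(gh, cl$dc, dparams$levels[[l]]$c1, dparams$levels[[l]]$c2)
    w <- cl$w
    gskips[[l]] <- db$gx[, , seq_len(w), drop = FALSE]
    gr <- db$gx[, , w + seq_len(w), drop = FALSE]
    ga <- gr * cl$m
    ub <- cpp_conv2d_bw(cl$u, dparams$levels[[l]]$up$W, ga,
                        dparams$levels[[l]]$up$k)
    gh <- cpp_upsample2_bw(ub$gx, cl$in_dim[1], cl$in_dim[2])
    g_levels[[l]] <- list(up = list(W = ub$gW, b = as.numeric(ub$gb)),
                          c1 = db$g1, c2 = db$g2)
  }
  list(gFA = gh, gskips = gskips,
       grads = list(levels = g_levels,
                    out = list(W = ob$gW, b = as.numeric(ob$gb))))
}

#' Forward pass through the network
#'
#' In training mode every decoder runs: the primary decoder on the raw
#' bottleneck features, each auxiliary decoder on an independently
#' noise-perturbed copy. In inference mode only the primary decoder runs and
#' no noise is applied.
#'
#' @param model An `mcl_net`.
#' @param x H x W x in_channels input array (PCA-reduced cube); spatial dims
#'   must be divisible by `2^depth`.
#' @param training Logical; run all decoders with feature noise?
#' @param noise_stream `rng_stream` feeding the noise draws (training only).
#' @return A list with `probs` (list of H x W x 2 probability maps — length
#'   `n_decoders` in training mode, 1 in inference mode; index 1 is the
#'   primary decoder) plus the caches needed for backprop.
#' @export
forward_mcl <- function(model, x, training = FALSE, noise_stream = NULL) {
  cfg <- model$cfg
  d <- dim(x)
  if (length(d) != 3L || d[3] != cfg$in_channels) {
    stop("input must be H x W x ", cfg$in_channels, call. = FALSE)
  }
  if (d[1] %% 2^cfg$depth != 0 || d[2] %% 2^cfg$depth != 0) {
    stop("spatial dims ", d[1], "x", d[2], " not divisible by 2^depth = ",
         2^cfg$depth, call. = FALSE)
  }
  enc <- encoder_fw(model$params$enc, x, cfg$depth)
  n_run <- if (training) cfg$n_decoders else 1L
  probs <- vector("list", n_run)
  dcaches <- vector("list", n_run)
  eps_list <- vector("list", n_run)
  for (dd in seq_len(n_run)) {
    FA_d <- enc$FA
    if (training && dd > 1) {
      sp <- cfg$noise[[dd - 1]]
      pr <- perturb_features(enc$FA, sp$mean, sp$sd, noise_stream,
                             cfg$noise_mode)
      FA_d <- pr$FA
      eps_list[[dd]] <- pr$eps
    }
    fw <- decoder_fw(model$params$dec[[dd]], FA_d, enc$skips, cfg$depth,
                     model$widths)
    probs[[dd]] <- fw$probs
    dcaches[[dd]] <- fw$cache
  }
  list(probs = probs, enc = enc, dcaches = dcaches, eps = eps_list)
}

# Backward pass: glogits_list[[d]] is dLoss/dlogits for decoder d (NULL if
# that decoder receives no gradient). Returns a full gradient tree.
backward_mcl <- function(model, fwd, glogits_list) {
  cfg <- model$cfg
  gFA <- NULL
  gskips <- vector("list", cfg$depth)
  grads <- zero_like(model$params)
  for (dd in seq_along(glogits_list)) {
    gl <- glogits_list[[dd]]
    if (is.null(gl)) next
    db <- decoder_bw(model$params$dec[[dd]], gl, fwd$dcaches[[dd]], cfg$depth)
    gFA_d <- db$gFA
    if (dd > 1 && cfg$noise_mode == "multiplicative") {
      gFA_d <- gFA_d * fwd$eps[[dd]]
    }
    gFA <- if (is.null(gFA)) gFA_d else gFA + gFA_d
    for (l in seq_len(cfg$depth)) {
      gskips[[l]] <- if (is.null(gskips[[l]])) db$gskips[[l]] else
        gskips[[l]] + db$gskips[[l]]
    }
    grads$dec[[dd]] <- tree_add(grads$dec[[dd]], db$grads)
  }
  if (!is.null(gFA)) {
    eb <- encoder_bw(model$params$enc, gFA, gskips, fwd$enc$cache, cfg$depth)
    grads$enc <- tree_add(grads$enc, eb$grads)
  }
  grads
}
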