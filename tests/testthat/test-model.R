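small_cfg <- function(n_decoders = 3, seed = 1, ...) {
  mcl_config(in_channels = 3, n_decoders = n_decoders, depth = 2,
             base_width = 4, seed = seed, ...)
}

test_that("model building is seeded and scales with decoder count", {
  m1 <- build_model(small_cfg(seed = 11))
  m2 <- build_model(small_cfg(seed = 11))
  expect_identical(m1$params, m2$params)
  m3 <- build_model(small_cfg(seed = 12))
  expect_false(identical(m1$params, m3$params))

  # n = 1 is a plain U-Net: one decoder, no noise specs
  u <- build_model(small_cfg(n_decoders = 1))
  expect_length(u$params$dec, 1L)
  expect_length(u$cfg$noise, 0L)

  # parameter count = encoder + n * decoder
  enc_n <- mclseg:::n_params(m1$params$enc)
  dec_n <- mclseg:::n_params(m1$params$dec[[1]])
  expect_identical(count_params(m1), enc_n + 3 * dec_n)
  expect_identical(count_params(u), enc_n + dec_n)
  expect_gt(count_params(m1), count_params(u))

  expect_error(mcl_config(n_decoders = 0), ">= 1")
  expect_error(mcl_config(n_decoders = 3,
                          noise = list(list(mean = 1, sd = 1.2))),
               "n_decoders - 1")
})

test_that("feature noise has the configured moments and degenerate limits", {
  FA <- array(rnorm(10 * 10 * 4), c(10, 10, 4))
  # sd = 0 degenerate cases
  add0 <- perturb_features(FA, mean = 1, sd = 0, mode = "additive")
  expect_equal(add0$FA, FA + 1)
  mul0 <- perturb_features(FA, mean = 1, sd = 0, mode = "multiplicative")
  expect_equal(mul0$FA, FA)
  # Monte-Carlo moment check at the trained noise level
  big <- array(0, c(100, 100, 100))  # 1e6 elements
  pr <- perturb_features(big, mean = 1, sd = 1.2, stream = rng_stream(99))
  eps <- pr$FA - big
  expect_lt(abs(mean(eps) - 1.0), 0.01)
  expect_lt(abs(sd(eps) - 1.2), 0.01)
  # stream-fed draws are reproducible
  pr2 <- perturb_features(big, mean = 1, sd = 1.2, stream = rng_stream(99))
  expect_identical(pr$FA, pr2$FA)
})

test_that("forward pass normalizes probabilities and gates decoders by mode", {
  m <- build_model(small_cfg())
  x <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
  fw <- forward_mcl(m, x, training = TRUE, noise_stream = rng_stream(5))
  expect_length(fw$probs, 3L)
  for (p in fw$probs) {
    expect_true(all(p >= 0))
    expect_lt(max(abs(p[, , 1] + p[, , 2] - 1)), 1e-5)
  }
  fi <- forward_mcl(m, x, training = FALSE)
  expect_length(fi$probs, 1L)
  expect_error(forward_mcl(m, array(0, c(15, 16, 3))), "divisible")
  expect_error(forward_mcl(m, array(0, c(16, 16, 2))), "H x W x 3")
})

test_that("decoders with shared weights and null noise emit identical maps", {
  cfg <- mcl_config(in_channels = 3, n_decoders = 3, depth = 2,
                    base_width = 4, seed = 2,
                    noise = list(list(mean = 0, sd = 0),
                                 list(mean = 0, sd = 0)),
                    noise_mode = "additive")
  m <- build_model(cfg)
  m$params$dec[[2]] <- m$params$dec[[1]]
  m$params$dec[[3]] <- m$params$dec[[1]]
  x <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
  fw <- forward_mcl(m, x, training = TRUE, noise_stream = rng_stream(1))
  expect_lt(max(abs(fw$probs[[1]] - fw$probs[[2]])), 1e-6)
  expect_lt(max(abs(fw$probs[[1]] - fw$probs[[3]])), 1e-6)
})

test_that("the primary decoder's input is never perturbed", {
  # with huge noise, auxiliaries diverge but the primary map matches the
  # inference map (which is noise-free by contract)
  cfg <- mcl_config(in_channels = 3, n_decoders = 2, depth = 2,
                    base_width = 4, seed = 3,
                    noise = list(list(mean = 0, sd = 50)))
  m <- build_model(cfg)
  x <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
  fw <- forward_mcl(m, x, training = TRUE, noise_stream = rng_stream(4))
  fi <- forward_mcl(m, x, training = FALSE)
  expect_identical(fw$probs[[1]], fi$probs[[1]])
})

test_that("backpropagated gradients match finite differences", {
  cfg <- mcl_config(in_channels = 2, n_decoders = 2, depth = 2,
                    base_width = 3, seed = 3,
                    noise = list(list(mean = 0.5, sd = 0)))
  m <- build_model(cfg)
  set.seed(21)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  y <- matrix(rbinom(64, 1, 0.5), 8, 8)
  base_fw <- forward_mcl(m, x, training = TRUE, noise_stream = rng_stream(1))
  pseudo0 <- soft_hard_labels(base_fw$probs, 0.5)
  loss_fn <- function(model) {
    fw <- forward_mcl(model, x, training = TRUE,
                      noise_stream = rng_stream(1))
    supervised_loss(fw$probs[[1]], y) +
      0.01 * multi_consistency_loss(fw$probs, pseudo0, "hard")
  }
  gl1 <- mclseg:::ce_dice_glogits(base_fw$probs[[1]], y)
  glu <- vector("list", 2)
  for (i in 1:2) {
    j <- 3 - i
    glu[[i]] <- 0.01 * mclseg:::ce_dice_glogits(base_fw$probs[[i]],
                                                pseudo0[[j]]$hard)
  }
  grads <- mclseg:::backward_mcl(m, base_fw,
                                 list(gl1 + glu[[1]], glu[[2]]))
  probe <- list(
    list(keys = list("enc", "levels", 1, "c1"), field = "W", idx = 4),
    list(keys = list("enc", "bottleneck", "c2"), field = "b", idx = 2),
    list(keys = list("dec", 1, "levels", 2, "up"), field = "W", idx = 6),
    list(keys = list("dec", 1, "out"), field = "b", idx = 1),
    list(keys = list("dec", 2, "levels", 1, "c2"), field = "W", idx = 5))
  get_leaf <- function(tree, keys) { for (k in keys) tree <- tree[[k]]; tree }
  set_scalar <- function(model, keys, field, idx, v) {
    f <- function(nd, ks) {
      if (!length(ks)) { nd[[field]][idx] <- v; return(nd) }
      nd[[ks[[1]]]] <- f(nd[[ks[[1]]]], ks[-1]); nd
    }
    model$params <- f(model$params, as.list(keys))
    model
  }
  eps <- 1e-6
  for (p in probe) {
    v0 <- get_leaf(m$params, p$keys)[[p$field]][p$idx]
    num <- (loss_fn(set_scalar(m, p$keys, p$field, p$idx, v0 + eps)) -
            loss_fn(set_scalar(m, p$keys, p$field, p$idx, v0 - eps))) /
      (2 * eps)
    ana <- get_leaf(grads, p$keys)[[p$field]][p$idx]
    expect_lt(abs(ana - num), 1e-6)
  }
})

test_that("an unlabeled step sends gradient to the encoder via every decoder", {
  cfg <- mcl_config(in_channels = 2, n_decoders = 3, depth = 2,
                    base_width = 3, seed = 5,
                    noise = list(list(mean = 1, sd = 1.2),
                                 list(mean = 1, sd = 1.5)))
  m <- build_model(cfg)
  set.seed(31)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  fw <- forward_mcl(m, x, training = TRUE, noise_stream = rng_stream(2))
  pseudo <- soft_hard_labels(fw$probs, 0.5)
  # gradient through one decoder at a time: encoder must receive signal
  for (d in 1:3) {
    gl <- vector("list", 3)
    j <- if (d == 1) 2 else 1
    gl[[d]] <- mclseg:::ce_dice_glogits(fw$probs[[d]], pseudo[[j]]$hard)
    g <- mclseg:::backward_mcl(m, fw, gl)
    enc_norm <- sum(abs(g$enc$levels[[1]]$c1$W))
    expect_gt(enc_norm, 0)
    # and only decoder d's parameters move
    for (dd in 1:3) {
      dec_norm <- sum(abs(g$dec[[dd]]$out$W))
      if (dd == d) expect_gt(dec_norm, 0) else expect_identical(dec_norm, 0)
    }
  }
})
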