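make_tiny_dataset <- function(td, n_scenes = 6, test_count = 2,
                              labeled_fraction = 0.5, seed = 31) {
  cfg <- synthetic_config(H = 32, W = 32, C = 6, n_scenes = n_scenes,
                          seed = seed)
  generate_dataset(cfg, td, labeled_fraction = labeled_fraction,
                   test_count = test_count)
}

tiny_model_cfg <- function(n_decoders = 3) {
  mcl_config(in_channels = 3, n_decoders = n_decoders, depth = 2,
             base_width = 4)
}

tiny_train_cfg <- function(epochs = 2, seed = 1) {
  train_config(epochs = epochs, crop_size = 32, seed = seed)
}

test_that("batch schedules cycle the labeled pool over the unlabeled epoch", {
  # the 10%-labeled regime: 6 labeled, 60 unlabeled, 1 epoch = 60 iterations
  sch <- make_batches(6, 60, epochs = 1, stream = rng_stream(3))
  expect_identical(nrow(sch), 60L)
  expect_identical(sort(unique(sch$unlabeled)), 1:60)
  expect_true(all(table(sch$unlabeled) == 1))
  lab_counts <- table(sch$labeled)
  expect_identical(sort(unique(names(lab_counts))), as.character(1:6))
  expect_true(all(abs(lab_counts - 10) <= 1))
  # deterministic given the stream seed
  sch2 <- make_batches(6, 60, epochs = 1, stream = rng_stream(3))
  expect_identical(sch, sch2)
  # supervised-only: no unlabeled column values
  sup <- make_batches(4, 0, epochs = 2, stream = rng_stream(3))
  expect_identical(nrow(sup), 8L)
  expect_true(all(is.na(sup$unlabeled)))
  expect_error(make_batches(0, 10, 1, rng_stream(1)), "no labeled")
})

test_that("training logs obey the loss bookkeeping identities", {
  td <- withr::local_tempdir()
  man <- make_tiny_dataset(td)
  fit <- train_mcl(man, tiny_model_cfg(), tiny_train_cfg(), quiet = TRUE)
  log <- fit$log
  # L = lambda * L_s + beta * L_u at every iteration
  w <- fit$train_cfg$weights
  expect_equal(log$L, w$lambda * log$L_s + log$beta * log$L_u,
               tolerance = 1e-6)
  # beta trace matches the closed-form schedule
  expect_equal(log$beta, warmup_beta(log$t, fit$t_max), tolerance = 1e-12)
  expect_equal(log$beta[nrow(log)], 0.001, tolerance = 1e-12)
  # t_max = epochs x unlabeled pool size
  expect_identical(fit$t_max, 2L * sum(man$split == "unlabeled"))
  expect_true(all(is.finite(log$L)))
})

test_that("a supervised-only fit trains on the labeled pool alone", {
  td <- withr::local_tempdir()
  man <- make_tiny_dataset(td)
  expect_message(
    fit <- train_mcl(man, tiny_model_cfg(n_decoders = 1), tiny_train_cfg()),
    "supervised-only")
  expect_identical(fit$t_max, 2L * sum(man$split == "labeled"))
  expect_true(all(is.na(fit$log$L_u)))
  expect_equal(fit$log$L, 0.5 * fit$log$L_s, tolerance = 1e-9)
})

test_that("training is reproducible and responds to the seed", {
  td <- withr::local_tempdir()
  man <- make_tiny_dataset(td)
  f1 <- train_mcl(man, tiny_model_cfg(), tiny_train_cfg(seed = 7),
                  quiet = TRUE, track_best = FALSE)
  f2 <- train_mcl(man, tiny_model_cfg(), tiny_train_cfg(seed = 7),
                  quiet = TRUE, track_best = FALSE)
  expect_identical(f1$log, f2$log)
  expect_identical(f1$model$params, f2$model$params)
  f3 <- train_mcl(man, tiny_model_cfg(), tiny_train_cfg(seed = 8),
                  quiet = TRUE, track_best = FALSE)
  expect_false(identical(f1$log$L, f3$log$L))
})

test_that("pseudo-label targets carry no gradient back to their decoder", {
  cfg <- mcl_config(in_channels = 2, n_decoders = 2, depth = 2,
                    base_width = 3, seed = 9,
                    noise = list(list(mean = 1, sd = 1.2)))
  m <- build_model(cfg)
  set.seed(41)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  fw <- forward_mcl(m, x, training = TRUE, noise_stream = rng_stream(6))
  pseudo <- soft_hard_labels(fw$probs, 0.5)
  # recompute targets from deep copies: gradients must be bit-identical
  pseudo_copy <- lapply(pseudo, function(p) {
    list(soft = p$soft + 0, hard = p$hard + 0L, decoder = p$decoder)
  })
  gl <- function(ps) {
    lapply(1:2, function(i) {
      mclseg:::ce_dice_glogits(fw$probs[[i]], ps[[3 - i]]$hard)
    })
  }
  g1 <- mclseg:::backward_mcl(m, fw, gl(pseudo))
  g2 <- mclseg:::backward_mcl(m, fw, gl(pseudo_copy))
  expect_identical(g1, g2)
})

test_that("supervised updates with beta = 0 leave auxiliary decoders fixed", {
  td <- withr::local_tempdir()
  man <- make_tiny_dataset(td)
  lab <- man[man$split == "labeled", ][1, ]
  cube <- read_cube(lab$cube)
  mask <- read_mask(lab$mask)
  pca <- fit_pca(cube, k = 3)
  x <- apply_pca(pca, cube)
  m <- build_model(tiny_model_cfg())
  w <- loss_weights(lambda = 1, beta_amplitude = 0)  # beta identically 0
  opt <- list(vel = mclseg:::zero_like(m$params), lr = 0.01, momentum = 0.9)
  st <- train_step(m, list(x = x, mask = unclass(mask)), x, w, opt,
                   t = 1, t_max = 10, noise_stream = rng_stream(2))
  expect_identical(st$model$params$dec[[2]], m$params$dec[[2]])
  expect_identical(st$model$params$dec[[3]], m$params$dec[[3]])
  expect_false(identical(st$model$params$dec[[1]], m$params$dec[[1]]))
  expect_false(identical(st$model$params$enc, m$params$enc))
  # and the update equals a supervised-only reference step with the same rng
  m1 <- build_model(tiny_model_cfg(n_decoders = 1))
  m1$params$enc <- m$params$enc
  m1$params$dec[[1]] <- m$params$dec[[1]]
  opt1 <- list(vel = mclseg:::zero_like(m1$params), lr = 0.01, momentum = 0.9)
  st1 <- train_step(m1, list(x = x, mask = unclass(mask)), NULL, w, opt1,
                    t = 1, t_max = 10, noise_stream = rng_stream(2))
  expect_equal(st1$model$params$dec[[1]], st$model$params$dec[[1]],
               tolerance = 1e-12)
  expect_equal(st1$model$params$enc, st$model$params$enc, tolerance = 1e-12)
})

test_that("tiled inference agrees with direct forward passes", {
  td <- withr::local_tempdir()
  man <- make_tiny_dataset(td)
  m <- build_model(tiny_model_cfg())
  pca <- fit_pca(lapply(man$cube[man$split == "labeled"], read_cube), k = 3)
  cube <- read_cube(man$cube[1])
  x <- apply_pca(pca, cube)
  # scene == one tile: identical to the direct forward pass
  direct <- forward_mcl(m, x, training = FALSE)$probs[[1]][, , 2]
  tiled <- predict_scene(m, cube, pca = pca, tile = 32)
  expect_lt(max(abs(tiled$prob - direct)), 1e-12)
  expect_identical(unclass(tiled$mask),
                   matrix(as.integer(direct > 0.5), 32, 32))
  # larger-than-tile scene: overlapping tiles cover every pixel
  big <- synthetic_config(H = 48, W = 48, C = 6, n_scenes = 1, seed = 77)
  sc <- generate_scene(big, 1)
  pca48 <- fit_pca(sc$cube, k = 3)
  pr <- predict_scene(m, sc$cube, pca = pca48, tile = 32, overlap = 0.5)
  expect_identical(dim(pr$prob), c(48L, 48L))
  expect_true(all(is.finite(pr$prob)))
  # constant input: overlap cannot change the (constant) prediction
  const <- array(0.3, c(48, 48, 3))
  p0 <- predict_scene(m, const, tile = 32, overlap = 0)
  p5 <- predict_scene(m, const, tile = 32, overlap = 0.5)
  expect_identical(unclass(p0$mask), unclass(p5$mask))
})

test_that("checkpoints roundtrip through disk", {
  td <- withr::local_tempdir()
  man <- make_tiny_dataset(td)
  fit <- train_mcl(man, tiny_model_cfg(), tiny_train_cfg(epochs = 1),
                   quiet = TRUE, out_dir = file.path(td, "run"))
  expect_true(file.exists(file.path(td, "run", "final.ckpt.rds")))
  expect_true(file.exists(file.path(td, "run", "training_log.csv")))
  back <- read_checkpoint(file.path(td, "run", "final.ckpt.rds"))
  expect_identical(back$model$params, fit$model$params)
  # tidy/glance/autoplot accessors
  expect_identical(nrow(glance(fit)), 1L)
  expect_true(all(c("component", "value") %in% names(tidy(fit))))
  expect_s3_class(autoplot(fit), "ggplot")
  pred <- predict_scene(fit, read_cube(man$cube[1]), tile = 32)
  truth <- read_mask(man$mask[1])
  expect_s3_class(plot_mask(pred, truth), "ggplot")
})
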