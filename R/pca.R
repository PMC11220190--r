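# PCA spectral band reduction.
#
# Pixel spectra pooled across the training cubes (labeled + unlabeled) are
# standardized per band and projected onto the leading k principal
# components; the fitted model is then frozen and applied unchanged to test
# scenes. Default k = 6 channels.

#' Fit a PCA band-reduction model
#'
#' Pools pixel spectra from all supplied cubes, optionally subsampling for
#' tractability, standardizes each band (mean 0, unit variance over the
#' pooled pixels), and computes the top-k principal components. Component
#' signs are fixed so each component's largest-magnitude loading is
#' positive, making fits reproducible.
#'
#' @param cubes A [hyper_cube] or list of them.
#' @param k Number of components to retain (default 6).
#' @param pixel_subsample Maximum number of pixels used for fitting
#'   (default 100000); subsampling is seeded.
#' @param seed Seed for the pixel subsample.
#' @return A `pca_bands` object with fields `band_means`, `band_scales`,
#'   `components` (k x C, orthonormal rows), `explained_variance_ratio`,
#'   and `wavelengths_nm`.
#' @export
fit_pca <- function(cubes, k = 6, pixel_subsample = 100000, seed = 0L) {
  if (inherits(cubes, "hyper_cube")) cubes <- list(cubes)
  stopifnot(length(cubes) >= 1, all(vapply(cubes, inherits, TRUE, "hyper_cube")))
  C <- dim(cubes[[1]]$data)[3]
  if (k > C) stop("k = ", k, " exceeds band count C = ", C, call. = FALSE)
  X <- do.call(rbind, lapply(cubes, function(cb) {
    d <- dim(cb$data)
    matrix(cb$data, d[1] * d[2], d[3])
  }))
  if (nrow(X) > pixel_subsample) {
    idx <- with_stream(rng_stream(seed), sample(nrow(X), pixel_subsample))
    X <- X[idx, , drop = FALSE]
  }
  mu <- colMeans(X)
  sc <- apply(X, 2, stats::sd)
  zero_var <- sc < 1e-12
  if (any(zero_var)) {
    warning("constant band(s) ", paste(which(zero_var), collapse = ", "),
            ": scale clamped to 1")
    sc[zero_var] <- 1
  }
  Z <- sweep(sweep(X, 2, mu), 2, sc, "/")
  p <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  comps <- t(p$rotation[, seq_len(k), drop = FALSE])  # k x C
  # sign convention: largest-magnitude loading positive
  for (r in seq_len(k)) {
    j <- which.max(abs(comps[r, ]))
    if (comps[r, j] < 0) comps[r, ] <- -comps[r, ]
  }
  evr <- p$sdev^2 / sum(p$sdev^2)
  structure(list(band_means = mu, band_scales = sc, components = comps,
                 explained_variance_ratio = evr[seq_len(k)],
                 wavelengths_nm = cubes[[1]]$wavelengths_nm),
            class = "pca_bands")
}

#' @export
print.pca_bands <- function(x, ...) {
  cat(sprintf("<pca_bands> %d components over %d bands; cumulative EVR %.4f\n",
              nrow(x$components), ncol(x$components),
              sum(x$explained_variance_ratio)))
  invisible(x)
}

#' Apply a fitted PCA model to a cube
#'
#' @param model A `pca_bands` model from [fit_pca()].
#' @param cube A [hyper_cube] (or bare H x W x C array) with the same band
#'   count the model was fitted on.
#' @return An H x W x k numeric array of component scores.
#' @export
apply_pca <- function(model, cube) {
  stopifnot(inherits(model, "pca_bands"))
  a <- if (inherits(cube, "hyper_cube")) cube$data else cube
  d <- dim(a)
  C <- ncol(model$components)
  if (d[3] != C) {
    stop("cube has ", d[3], " bands but model expects ", C, call. = FALSE)
  }
  X <- matrix(a, d[1] * d[2], d[3])
  Z <- sweep(sweep(X, 2, model$band_means), 2, model$band_scales, "/")
  S <- Z %*% t(model$components)
  array(S, c(d[1], d[2], nrow(model$components)))
}

#' Save / load a PCA band-reduction model
#'
#' @param model A `pca_bands` object.
#' @param path RDS file path.
#' @return `write_pca` returns the path invisibly; `read_pca` the model.
#' @export
write_pca <- function(model, path) {
  stopifnot(inherits(model, "pca_bands"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname write_pca
#' @export
read_pca <- function(path) {
  structure(readRDS(path), class = "pca_bands")
}
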