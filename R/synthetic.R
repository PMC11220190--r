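# Synthetic hyperspectral pathology scenes.
#
# Emulates the structure of microscopic hyperspectral tumor imagery at desk
# scale: two tissue classes (normal / tumor) whose mean reflectance spectra
# are smooth functions of wavelength over 550-1000 nm, tumor regions drawn
# as smooth blobs or connected annuli, plus three noise sources — per-pixel
# spectral jitter, independent per-pixel/band Gaussian noise, and a shared
# band-correlated offset (which gives PCA something non-trivial to remove).

gaussian_bumps <- function(wl, baseline, bumps) {
  s <- rep(baseline, length(wl))
  for (b in bumps) s <- s + b$amp * exp(-((wl - b$center) / b$width)^2)
  s
}

#' Default class spectral signatures
#'
#' Mean reflectance spectra for normal and tumor tissue, each a baseline plus
#' at most three Gaussian bumps over wavelength. The two spectra are smooth,
#' non-negative, and separated so that nearest-mean classification is
#' possible — the spectral-contrast property the segmentation method relies
#' on.
#'
#' @param wavelengths_nm Band-center wavelengths.
#' @return A list with matrices/vectors `normal` and `tumor` (length C).
#' @export
default_signatures <- function(wavelengths_nm) {
  list(
    normal = gaussian_bumps(wavelengths_nm, 0.30, list(
      list(amp = 0.45, center = 620, width = 60),
      list(amp = 0.25, center = 850, width = 90))),
    tumor = gaussian_bumps(wavelengths_nm, 0.25, list(
      list(amp = 0.55, center = 700, width = 70),
      list(amp = 0.35, center = 930, width = 80)))
  )
}

#' Synthetic dataset configuration
#'
#' @param H,W,C Scene height, width, and number of spectral bands.
#' @param wl_range Wavelength range in nm; bands are uniformly spaced.
#' @param n_scenes Number of scenes in the dataset.
#' @param morphology Tumor shapes to draw from: `"blob"`, `"ring"`, or both
#'   (scenes alternate deterministically).
#' @param f_range Tumor area fraction range `[f_lo, f_hi]`, a subset of (0,1).
#' @param sigma_pix Per-pixel, per-band independent Gaussian noise sd.
#' @param sigma_band Sd of the shared band-correlated offset.
#' @param sigma_spec Within-class spectral variation scale (per-pixel
#'   multiplicative jitter of the class spectrum).
#' @param modulation_amp Amplitude of the smooth spatial brightness
#'   modulation field (default 0.1; 0 disables it).
#' @param separation Minimum required max band-wise difference between the
#'   two class mean spectra.
#' @param seed Integer seed; all generation is deterministic given it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(H = 64, W = 64, C = 16,
                             wl_range = c(550, 1000),
                             n_scenes = 80,
                             morphology = c("blob", "ring"),
                             f_range = c(0.15, 0.45),
                             sigma_pix = 0.02,
                             sigma_band = 0.05,
                             sigma_spec = 0.03,
                             modulation_amp = 0.1,
                             separation = 0.05,
                             seed = 0L) {
  stopifnot(C >= 3, H >= 8, W >= 8,
            f_range[1] > 0, f_range[1] <= f_range[2], f_range[2] < 1,
            sigma_pix >= 0, sigma_band >= 0, sigma_spec >= 0,
            modulation_amp >= 0)
  morphology <- match.arg(morphology, c("blob", "ring"), several.ok = TRUE)
  wl <- seq(wl_range[1], wl_range[2], length.out = C)
  sig <- default_signatures(wl)
  sep <- max(abs(sig$tumor - sig$normal))
  if (sep < separation) {
    stop("class spectra separation ", signif(sep, 3),
         " below required ", separation, call. = FALSE)
  }
  structure(list(H = H, W = W, C = C, wavelengths_nm = wl,
                 n_scenes = n_scenes, morphology = morphology,
                 f_range = f_range, sigma_pix = sigma_pix,
                 sigma_band = sigma_band, sigma_spec = sigma_spec,
                 modulation_amp = modulation_amp,
                 signatures = sig, seed = seed),
            class = "synthetic_config")
}

# Smooth 2-D field: sum of a few random low-frequency cosines, scaled to
# roughly unit amplitude. Used for brightness modulation and blob wobble.
smooth_field <- function(H, W, n_waves = 4) {
  xs <- (seq_len(W) - 0.5) / W
  ys <- (seq_len(H) - 0.5) / H
  f <- matrix(0, H, W)
  for (k in seq_len(n_waves)) {
    fx <- runif(1, 0.5, 2.5); fy <- runif(1, 0.5, 2.5)
    ph <- runif(2, 0, 2 * pi); amp <- runif(1, 0.3, 1)
    f <- f + amp * outer(cos(2 * pi * fy * ys + ph[1]),
                         cos(2 * pi * fx * xs + ph[2]))
  }
  f / n_waves
}

# Draw a tumor mask of the requested morphology, rescaling the shape until
# its measured area fraction lands in [f_lo, f_hi].
draw_tumor_mask <- function(H, W, morphology, f_range, max_tries = 25) {
  f_target <- runif(1, f_range[1], f_range[2])
  ii <- matrix(seq_len(H), H, W)
  jj <- matrix(seq_len(W), H, W, byrow = TRUE)
  for (try in seq_len(max_tries)) {
    cy <- runif(1, 0.35, 0.65) * H
    cx <- runif(1, 0.35, 0.65) * W
    theta <- atan2(ii - cy, jj - cx)
    # radial wobble: low-order harmonics keep the boundary smooth and the
    # region simply connected
    a <- runif(2, -0.15, 0.15); ph <- runif(2, 0, 2 * pi)
    wob <- 1 + a[1] * cos(2 * theta + ph[1]) + a[2] * cos(3 * theta + ph[2])
    r <- sqrt((ii - cy)^2 + (jj - cx)^2)
    scale <- sqrt(f_target * H * W / pi)  # initial radius guess
    for (adj in 1:8) {
      if (morphology == "blob") {
        m <- r <= scale * wob
      } else {
        m <- r <= scale * wob & r >= 0.45 * scale * wob
      }
      f_meas <- mean(m)
      if (f_meas >= f_range[1] && f_meas <= f_range[2]) {
        return(matrix(as.integer(m), H, W))
      }
      if (f_meas <= 0) { scale <- scale * 1.5; next }
      scale <- scale * sqrt(f_target / f_meas)
    }
  }
  stop("could not draw a ", morphology, " with area fraction in [",
       f_range[1], ", ", f_range[2], "] at ", H, "x", W, call. = FALSE)
}

#' Generate one synthetic scene
#'
#' Deterministic given `(cfg$seed, scene_index)`: the same pair always yields
#' a bit-identical cube and mask. Each pixel's spectrum is its class mean,
#' scaled by a smooth spatial brightness modulation and per-pixel jitter,
#' plus independent Gaussian noise and a shared per-band offset; values are
#' clamped at zero so reflectance stays non-negative.
#'
#' @param cfg A [synthetic_config].
#' @param scene_index 1-based scene index.
#' @return A list with elements `cube` ([hyper_cube]) and `mask`
#'   ([label_mask]).
#' @export
generate_scene <- function(cfg, scene_index) {
  stopifnot(inherits(cfg, "synthetic_config"), scene_index >= 1)
  stream <- rng_stream(mix_seed(cfg$seed, scene_index))
  with_stream(stream, {
    H <- cfg$H; W <- cfg$W; C <- cfg$C
    morph <- cfg$morphology[((scene_index - 1) %% length(cfg$morphology)) + 1]
    mask <- draw_tumor_mask(H, W, morph, cfg$f_range)
    modulation <- 1 + cfg$modulation_amp * smooth_field(H, W)
    jitter <- 1 + cfg$sigma_spec * rnorm(H * W)
    band_offset <- cfg$sigma_band * rnorm(C)
    spec <- rbind(cfg$signatures$normal, cfg$signatures$tumor)  # 2 x C
    px_spec <- spec[as.vector(mask) + 1L, , drop = FALSE]       # (H*W) x C
    px_spec <- px_spec * (as.vector(modulation) * jitter)
    px_spec <- px_spec +
      matrix(rnorm(H * W * C, sd = cfg$sigma_pix), H * W, C) +
      matrix(band_offset, H * W, C, byrow = TRUE)
    cube <- array(pmax(px_spec, 0), c(H, W, C))
    list(cube = hyper_cube(cube, cfg$wavelengths_nm,
                           sprintf("scene_%03d", scene_index)),
         mask = label_mask(mask))
  })
}

#' Generate and write a synthetic dataset
#'
#' Writes cubes, masks, and a manifest under `out_dir`. The last
#' `test_count` scenes form the test split; of the remaining training
#' scenes, `floor(labeled_fraction * n_train)` are labeled (chosen by a
#' seeded draw) and the rest are unlabeled. Masks of unlabeled scenes are
#' still written to disk for oracle evaluation but are not listed in the
#' manifest, so training never sees them.
#'
#' @param cfg A [synthetic_config].
#' @param out_dir Output directory (created if needed).
#' @param labeled_fraction Fraction of training scenes that keep their
#'   labels, in (0, 1].
#' @param test_count Number of test scenes.
#' @param dialect Cube dialect passed to [write_cube()].
#' @return The manifest tibble (also written to `out_dir/manifest.csv`).
#' @export
generate_dataset <- function(cfg, out_dir, labeled_fraction = 0.10,
                             test_count = 14, dialect = "rds") {
  stopifnot(inherits(cfg, "synthetic_config"),
            labeled_fraction > 0, labeled_fraction <= 1,
            cfg$n_scenes > test_count)
  n_train <- cfg$n_scenes - test_count
  n_labeled <- floor(labeled_fraction * n_train)
  if (n_labeled < 1) {
    stop("labeled_fraction ", labeled_fraction, " leaves zero labeled scenes",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  labeled_idx <- with_stream(rng_stream(mix_seed(cfg$seed, 0L)),
                             sort(sample(n_train, n_labeled)))
  ext <- if (dialect == "rds") ".rds" else ".img"
  rows <- vector("list", cfg$n_scenes)
  for (i in seq_len(cfg$n_scenes)) {
    sc <- generate_scene(cfg, i)
    cube_path <- file.path(out_dir, paste0(sc$cube$scene_id, ext))
    mask_path <- file.path(out_dir, paste0(sc$cube$scene_id, "_mask.png"))
    write_cube(sc$cube, cube_path, dialect = dialect)
    write_mask(sc$mask, mask_path)
    split <- if (i > n_train) "test" else
      if (i %in% labeled_idx) "labeled" else "unlabeled"
    rows[[i]] <- tibble::tibble(
      scene_id = sc$cube$scene_id, cube = cube_path,
      mask = if (split == "unlabeled") "" else mask_path, split = split)
  }
  manifest <- dplyr::bind_rows(rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  load_manifest(file.path(out_dir, "manifest.csv"), quiet = TRUE)
}
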