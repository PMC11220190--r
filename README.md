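# mclseg

Semi-supervised tumor segmentation for microscopic hyperspectral pathology
images in R.

Pixel-accurate tumor annotation of histopathology is expensive, so most
hyperspectral pathology datasets contain a handful of labeled scenes and
many unlabeled ones. `mclseg` implements a multi-decoder consistency
network for exactly that regime: a single shared U-Net encoder feeds `n`
independent decoders, the auxiliary decoders see Gaussian-noise-perturbed
bottleneck features, and the decoders teach one another on unlabeled data
through a pairwise consistency objective built from sharpened pseudo-labels.
The package is aimed at image-analysis researchers who want a complete,
CPU-runnable reference implementation of the method — including data I/O,
PCA band reduction, a synthetic benchmark generator, training, inference,
and evaluation.

## The model

Each scene is a reflectance cube `X ∈ R^{H×W×C}` (here C bands over
550–1000 nm) with, for labeled scenes, a binary mask `Y ∈ {0,1}^{H×W}`
(1 = tumor). Spectra are first reduced to `k` channels (default 6) by PCA
fitted on pooled training pixels.

Training draws one labeled and one unlabeled crop per iteration:

* **Supervised loss** (primary decoder only):
  `L_s = L_CE(y_seg, Y) + L_Dice(y_seg, Y)`.
* **Soft-Hard pseudo-labels**: each decoder's tumor probability `p` is
  sharpened, `P_S = p^{1/T} / (p^{1/T} + (1-p)^{1/T})` with `T = 0.5`,
  then thresholded, `P_H = argmax(P_S)`. Pseudo-labels are detached: no
  gradient flows through the target side.
* **Multi-consistency loss** over all ordered decoder pairs `i ≠ j`:
  `L_u = Σ_{i≠j} [ L_CE(y_seg^i, P_H^j) + L_Dice(y_seg^i, P_H^j) ]`.
* **Total**: `L = λ L_s + β(t) L_u`, with `λ = 0.5` and the Gaussian
  warm-up `β(t) = 0.001 · exp(−5 (1 − t/t_max)²)`, so unreliable early
  pseudo-labels carry almost no weight and `β(t_max) = 0.001`.

Default settings: `n = 3` decoders, additive
feature noise `N(1, 1.2²)` and `N(1, 1.5²)` on the two auxiliary
bottleneck inputs, SGD with learning rate 0.01 and momentum 0.9, batch
1 labeled + 1 unlabeled, 100 epochs. At inference only the primary decoder
runs, on unperturbed features, with overlapping-tile probability averaging
for scenes larger than one tile.

The network itself (U-Net with shared encoder, backprop, momentum SGD) is
implemented in the package, with the convolution / pooling / upsampling
kernels in C++ (RcppArmadillo); gradients are tested against finite
differences.

## Worked example

Everything below runs on a synthetic benchmark shipped with the package:
seeded hyperspectral scenes (two tissue classes with smooth Gaussian-bump
spectra, blob/ring tumor morphologies, pixel, spectral, and band-correlated
noise) so no external data are needed.

```r
library(mclseg)
cfg <- synthetic_config(H = 64, W = 64, C = 16, n_scenes = 10, seed = 42)
man <- generate_dataset(cfg, "demo_data", labeled_fraction = 0.25, test_count = 2)
fit <- train_mcl(man,
                 mcl_config(in_channels = 6, n_decoders = 3, depth = 3, base_width = 8),
                 train_config(epochs = 10, crop_size = 64, seed = 42),
                 quiet = TRUE)
glance(fit)
#> # A tibble: 1 × 10
#>   n_decoders depth base_width t_max final_L_s final_L_u final_beta final_L
#>        <dbl> <dbl>      <dbl> <int>     <dbl>     <dbl>      <dbl>   <dbl>
#> 1          3     3          8    60   0.00501      26.2      0.001  0.0287
evaluate_model(fit, man, split = "test")
#> # A tibble: 3 × 5
#>   scene_id     OA    AA  Dice  MIoU
#>   <chr>     <dbl> <dbl> <dbl> <dbl>
#> 1 scene_009 0.976 0.978 0.974 0.952
#> 2 scene_010 0.987 0.991 0.977 0.969
#> 3 POOLED    0.981 0.985 0.975 0.961
```

`glance()` summarizes the fit: after `t_max = 60` iterations the warm-up
weight has reached its plateau (`final_beta = 0.001`), the supervised loss
is near zero, and `final_L` recombines the components as
`λ·L_s + β·L_u`. `evaluate_model()` reports overall accuracy, average
(class-balanced) accuracy, hard Dice, and mean IoU per test scene plus a
`POOLED` row computed from confusion counts summed over all test pixels —
here the model segments ~97.5% of tumor area correctly (Dice 0.975).
`autoplot(fit)` draws the loss curves and `plot_mask(pred, truth)` compares
masks.

A command-line interface wraps the same functions:

```sh
mclseg=$(Rscript -e 'cat(system.file("cli", "mclseg", package = "mclseg"))')
$mclseg generate --out demo_data --seed 42
$mclseg train --manifest demo_data/manifest.csv --out run --loss.lambda 0.5
$mclseg evaluate --checkpoint run/final.ckpt.rds --manifest demo_data/manifest.csv --out run
```

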