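# Pixel-level evaluation metrics. Tumor pixels are the positive class.
# Headline numbers pool confusion counts over all test pixels (micro
# aggregation); per-scene values are reported alongside for inspection.

#' Confusion counts between prediction and truth
#'
#' @param pred,truth Binary H x W masks ([label_mask] or matrix); tumor (1)
#'   is the positive class.
#' @return A `confusion_counts` list with integer fields `TP`, `TN`, `FP`,
#'   `FN` that partition the pixels.
#' @export
confusion_counts <- function(pred, truth) {
  p <- as.integer(unclass(pred)); y <- as.integer(unclass(truth))
  if (length(p) != length(y) || !identical(dim(unclass(pred)), dim(unclass(truth)))) {
    stop("prediction/truth shape mismatch", call. = FALSE)
  }
  stopifnot(all(p %in% 0:1), all(y %in% 0:1))
  structure(list(TP = sum(p == 1 & y == 1), TN = sum(p == 0 & y == 0),
                 FP = sum(p == 1 & y == 0), FN = sum(p == 0 & y == 1)),
            class = "confusion_counts")
}

counts_total <- function(c) c$TP + c$TN + c$FP + c$FN

#' Overall accuracy
#'
#' `OA = (TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param c A [confusion_counts].
#' @return Fraction in `[0, 1]`.
#' @export
overall_accuracy <- function(c) {
  n <- counts_total(c)
  if (n == 0) stop("empty counts", call. = FALSE)
  (c$TP + c$TN) / n
}

#' Average (class-balanced) accuracy
#'
#' `AA = (TP/(TP+FN) + TN/(FP+TN)) / 2`. If a truth class is absent, its
#' recall is defined as 1 when no pixels were falsely assigned to it and 0
#' otherwise; a message notes the convention.
#'
#' @inheritParams overall_accuracy
#' @return Fraction in `[0, 1]`.
#' @export
average_accuracy <- function(c) {
  recall <- function(tp, fn, fp, cls) {
    if (tp + fn == 0) {
      message("truth has no ", cls, " pixels; recall defined as ",
              as.integer(fp == 0))
      return(as.numeric(fp == 0))
    }
    tp / (tp + fn)
  }
  (recall(c$TP, c$FN, c$FP, "tumor") + recall(c$TN, c$FP, c$FN, "normal")) / 2
}

#' Mean intersection over union
#'
#' `MIoU = (TP/(TP+FP+FN) + TN/(FP+FN+TN)) / 2`.
#'
#' @inheritParams overall_accuracy
#' @return Fraction in `[0, 1]`.
#' @export
mean_iou <- function(c) {
  d1 <- c$TP + c$FP + c$FN
  d2 <- c$FP + c$FN + c$TN
  if (d1 == 0 && d2 == 0) stop("empty image: both IoU denominators zero",
                               call. = FALSE)
  iou <- function(num, den) if (den == 0) 1 else num / den
  (iou(c$TP, d1) + iou(c$TN, d2)) / 2
}

#' Dice coefficient (hard)
#'
#' `Dice = 2 TP / (2 TP + FP + FN)` on thresholded predictions, tumor class.
#' When neither truth nor prediction contains tumor the coefficient is
#' defined as 1 (noted by a message).
#'
#' @inheritParams overall_accuracy
#' @return Fraction in `[0, 1]`.
#' @export
dice_coefficient <- function(c) {
  den <- 2 * c$TP + c$FP + c$FN
  if (den == 0) {
    message("no tumor in truth or prediction; Dice defined as 1")
    return(1)
  }
  2 * c$TP / den
}

metrics_row <- function(c) {
  tibble::tibble(OA = overall_accuracy(c), AA = average_accuracy(c),
                 Dice = dice_coefficient(c), MIoU = mean_iou(c))
}

#' Evaluate a trained model on a manifest split
#'
#' Runs tiled primary-decoder inference on every scene of the chosen split,
#' compares against the ground-truth masks, and reports per-scene metrics
#' plus a `POOLED` row computed from confusion counts summed over all
#' pixels.
#'
#' @param fit An `mcl_fit` from [train_mcl()] (or a bare `mcl_net` plus a
#'   `pca` argument).
#' @param manifest Manifest tibble from [load_manifest()].
#' @param split Which split to evaluate (default `"test"`).
#' @param pca Optional `pca_bands` model; defaults to the one stored in
#'   `fit`.
#' @param tile,overlap Tiling parameters passed to [predict_scene()].
#' @param csv Optional path; when given, the metric table is also written
#'   as CSV.
#' @return A tibble with columns `scene_id`, `OA`, `AA`, `Dice`, `MIoU`;
#'   the final row has `scene_id == "POOLED"`.
#' @export
evaluate_model <- function(fit, manifest, split = "test", pca = NULL,
                           tile = NULL, overlap = 0.5, csv = NULL) {
  model <- if (inherits(fit, "mcl_fit")) fit$model else fit
  pca <- pca %||% if (inherits(fit, "mcl_fit")) fit$pca else NULL
  rows <- manifest[manifest$split == split, ]
  if (nrow(rows) == 0) stop("no scenes in split '", split, "'", call. = FALSE)
  if (any(rows$mask == "")) {
    stop("scenes without masks cannot be evaluated: ",
         paste(rows$scene_id[rows$mask == ""], collapse = ", "),
         call. = FALSE)
  }
  pooled <- list(TP = 0, TN = 0, FP = 0, FN = 0)
  per_scene <- purrr::map(seq_len(nrow(rows)), function(i) {
    cube <- read_cube(rows$cube[i])
    truth <- read_mask(rows$mask[i])
    pred <- predict_scene(model, cube, pca = pca, tile = tile,
                          overlap = overlap)
    cc <- confusion_counts(pred$mask, truth)
    pooled$TP <<- pooled$TP + cc$TP; pooled$TN <<- pooled$TN + cc$TN
    pooled$FP <<- pooled$FP + cc$FP; pooled$FN <<- pooled$FN + cc$FN
    dplyr::bind_cols(tibble::tibble(scene_id = rows$scene_id[i]),
                     metrics_row(cc))
  })
  pooled <- structure(pooled, class = "confusion_counts")
  out <- dplyr::bind_rows(
    dplyr::bind_rows(per_scene),
    dplyr::bind_cols(tibble::tibble(scene_id = "POOLED"),
                     metrics_row(pooled)))
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
  out
}
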