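# broom-style accessors and plots for fitted objects.

#' Tidy the training log of a fit
#'
#' @param x An `mcl_fit`.
#' @param ... Unused.
#' @return A long tibble with columns `t`, `epoch`, `component`
#'   (`L_s`, `L_u`, `beta`, `L`), and `value`.
#' @export
tidy.mcl_fit <- function(x, ...) {
  tidyr::pivot_longer(x$log, cols = c("L_s", "L_u", "beta", "L"),
                      names_to = "component", values_to = "value")
}

#' One-row summary of a fit
#'
#' @param x An `mcl_fit`.
#' @param ... Unused.
#' @return A one-row tibble: decoder count, iterations, final loss
#'   components, and best labeled-scene Dice.
#' @export
glance.mcl_fit <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  tibble::tibble(n_decoders = x$model_cfg$n_decoders,
                 depth = x$model_cfg$depth,
                 base_width = x$model_cfg$base_width,
                 t_max = x$t_max,
                 final_L_s = last$L_s, final_L_u = last$L_u,
                 final_beta = last$beta, final_L = last$L,
                 best_labeled_dice = x$best_dice,
                 n_params = count_params(x$model))
}

#' Plot training-loss curves
#'
#' @param object An `mcl_fit`.
#' @param ... Unused.
#' @return A ggplot: loss components against iteration (the warm-up weight
#'   on its own facet scale).
#' @export
autoplot.mcl_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value,
                                   colour = .data$component)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL,
                  title = "Training loss components") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot a predicted mask against the ground truth
#'
#' @param pred A [label_mask] (or `predict_scene()` output).
#' @param truth Optional ground-truth [label_mask].
#' @return A ggplot raster panel (prediction, and truth when given).
#' @export
plot_mask <- function(pred, truth = NULL) {
  if (is.list(pred) && !is.null(pred$mask)) pred <- pred$mask
  as_df <- function(m, panel) {
    m <- unclass(m)
    tibble::tibble(row = rep(seq_len(nrow(m)), ncol(m)),
                   col = rep(seq_len(ncol(m)), each = nrow(m)),
                   class = factor(as.vector(m), 0:1, c("normal", "tumor")),
                   panel = panel)
  }
  df <- as_df(pred, "prediction")
  if (!is.null(truth)) df <- dplyr::bind_rows(df, as_df(truth, "truth"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::scale_fill_manual(values = c(normal = "grey85",
                                          tumor = "firebrick")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 .data
NULL
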