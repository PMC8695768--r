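phase_labels <- c(n_cambial = "cambial", n_enlarging = "enlarging",
                  n_thickening = "wall-thickening", n_mature = "mature",
                  n_total = "total")

#' Plot intra-annual phase dynamics of an observation table
#'
#' Faceted view of the seasonal trajectories of each developmental phase,
#' with per-stand smoothed curves overlaid on the raw per-tree counts.
#' Cambial and enlarging panels typically show the bimodal within-season
#' pattern; wall-thickening is bell-shaped and mature/total S-shaped.
#'
#' @param observations Long-format observation table (see
#'   [generate_tree()]).
#' @param phases Which count columns to show.
#' @param span Smoothing span for the overlay curves.
#' @return A ggplot object.
#' @export
plot_phase_dynamics <- function(observations,
                                phases = c("n_cambial", "n_enlarging",
                                           "n_thickening", "n_mature",
                                           "n_total"),
                                span = 0.25) {
  long <- observations |>
    tidyr::pivot_longer(dplyr::all_of(phases),
                        names_to = "phase", values_to = "cells") |>
    dplyr::mutate(phase = factor(phase_labels[.data$phase],
                                 levels = unname(phase_labels[phases])))
  ggplot2::ggplot(long, ggplot2::aes(.data$doy, .data$cells,
                                     colour = .data$stand_id)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.7) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, span = span,
                         se = FALSE, linewidth = 0.7) +
    ggplot2::facet_wrap(~phase, scales = "free_y") +
    ggplot2::labs(x = "Day of year", y = "Cells", colour = "Stand") +
    ggplot2::theme_minimal()
}

#' Plot a fitted stand model over its observations
#'
#' Observed counts per tree with the population Gompertz curve (solid)
#' and, optionally, the tree-level conditional curves (dashed).
#'
#' @param object An [fit_stand()] result.
#' @param show_trees Overlay per-tree conditional curves?
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.xylo_fit <- function(object, show_trees = TRUE, ...) {
  d <- object$data
  grid <- tibble::tibble(doy = seq(min(d$doy), max(d$doy), length.out = 200))
  grid$pop <- predict(object, grid$doy)
  gg <- ggplot2::ggplot(d, ggplot2::aes(.data$doy, .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$tree_id), alpha = 0.6) +
    ggplot2::geom_line(data = grid, ggplot2::aes(.data$doy, .data$pop),
                       inherit.aes = FALSE, linewidth = 0.9)
  if (show_trees && length(object$tree_effects) > 1) {
    tree_curves <- purrr::map_dfr(names(object$tree_effects), function(id) {
      tibble::tibble(tree_id = id, doy = grid$doy,
                     y = predict(object, grid$doy, tree_id = id))
    })
    gg <- gg + ggplot2::geom_line(
      data = tree_curves,
      ggplot2::aes(.data$doy, .data$y, colour = .data$tree_id),
      linetype = "dashed", linewidth = 0.4)
  }
  gg + ggplot2::labs(
    x = "Day of year", y = paste0("Cells (", object$response, ")"),
    colour = "Tree",
    title = sprintf("Gompertz stand fit%s: A = %.1f, beta = %.2f, k = %.4f",
                    if (is.na(object$stand_id)) "" else
                      paste0(" (", object$stand_id, ")"),
                    object$fixed$A, object$fixed$beta, object$fixed$k)) +
    ggplot2::theme_minimal()
}

#' Plot an LMG relative-importance decomposition
#'
#' @param object An [lmg_importance()] result.
#' @param ... Unused.
#' @return A ggplot object (bar chart of normalised R² shares).
#' @export
autoplot.lmg_importance <- function(object, ...) {
  ggplot2::ggplot(object$contributions,
                  ggplot2::aes(.data$predictor, 100 * .data$lmg_normalized)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Share of explained variance (%)",
                  title = sprintf("LMG decomposition (R² = %.2f)",
                                  object$total_r_squared)) +
    ggplot2::theme_minimal()
}
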