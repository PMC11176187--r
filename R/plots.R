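#' Heatmap of mean approximation error across the bias-degree grid
#'
#' One tile per `(p, K)` cell (cell mean of the MAE), faceted by Taylor
#' order.
#'
#' @param object a [run_approximability_grid()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.approx_grid <- function(object, ...) {
  cell <- object |>
    dplyr::group_by(.data$K, .data$p, .data$order) |>
    dplyr::summarise(mae = mean(.data$mae), .groups = "drop")
  ggplot2::ggplot(cell, ggplot2::aes(x = factor(.data$p), y = factor(.data$K),
                                     fill = .data$mae)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~order, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 0.25)) +
    ggplot2::labs(x = "bias p", y = "in-degree K",
                  fill = "MAE") +
    ggplot2::theme_minimal()
}

#' Coefficient traces along a LASSO path
#'
#' @param object a [lasso_path()].
#' @param ... unused.
#' @return A ggplot object: standardized coefficients against the penalty
#'   (log scale, decreasing to the right).
#' @export
autoplot.lasso_path <- function(object, ...) {
  ggplot2::ggplot(object$path,
                  ggplot2::aes(x = .data$alpha, y = .data$estimate,
                               colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = "penalty alpha (log scale)",
                  y = "standardized coefficient") +
    ggplot2::theme_minimal()
}

#' Boxplots of approximability under constrained canalization
#'
#' Renders [run_depth_experiment()] / [run_layer_experiment()] tables as
#' per-condition MAE boxplots coloured by Taylor order.
#'
#' @param data a tibble with columns `order`, `mae` and one of `min_depth` /
#'   `layer_structure`.
#' @return A ggplot object.
#' @export
plot_canalization_mae <- function(data) {
  cond <- if ("min_depth" %in% names(data)) "min_depth" else "layer_structure"
  ggplot2::ggplot(data,
                  ggplot2::aes(x = factor(.data[[cond]]), y = .data$mae,
                               fill = factor(.data$order))) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = cond, y = "mean approximation error",
                  fill = "Taylor order") +
    ggplot2::theme_minimal()
}
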