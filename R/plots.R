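# ggplot2 views of the main result types.

#' Degree distribution on log-log axes
#'
#' Plots the empirical degree distribution P(k) against degree on log10
#' axes with the least-squares power-law fit overlaid — the standard
#' scale-free diagnostic.
#'
#' @param network Any object accepted by [network_summary()].
#' @return A ggplot object.
#' @export
plot_degree_distribution <- function(network) {
  g <- as_dcnet_igraph(network)
  deg <- igraph::degree(g)
  fit <- power_law_fit(deg[deg > 0])
  ggplot2::ggplot(fit$table, ggplot2::aes(.data$degree, .data$probability)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "degree k", y = "P(k)",
      title = sprintf("Degree distribution (slope %.2f, R² %.2f)",
                      fit$slope, fit$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_degree_distribution Greedy-search score trace of a
#'   subnetwork: combined score against accepted additions.
#' @param object A `dc_subnetwork`.
#' @param ... Unused.
#' @export
autoplot.dc_subnetwork <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(.data$step, .data$score)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "accepted addition", y = "combined score D",
      title = sprintf("Greedy trace, seed %s", object$seed)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_degree_distribution Activity heatmap: subnetworks by
#'   samples, faceted by condition.
#' @export
autoplot.activity_matrix <- function(object, ...) {
  tidy(object) %>%
    ggplot2::ggplot(ggplot2::aes(.data$sample_id, .data$subnetwork,
                                 fill = .data$activity)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(~condition, scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_gradient2(low = "steelblue", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Subnetwork activity (%s)", object$method)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
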