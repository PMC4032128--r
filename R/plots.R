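# ggplot2 displays for the main result types

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Biplot of a trait PCA
#'
#' Species scores on two principal components with variable loadings as
#' radiating segments, the standard display for asking which trait
#' combinations separate species groups.
#'
#' @param object A `trait_pca` from [pca_traits()].
#' @param components Two components to display (default PC1, PC2).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.trait_pca <- function(object, components = c("PC1", "PC2"), ...) {
  sc <- object$scores
  ld <- as.data.frame(object$loadings[, components, drop = FALSE])
  ld$variable <- rownames(object$loadings)
  scale_f <- max(abs(sc[[components[1]]]), abs(sc[[components[2]]]))
  pct <- round(100 * object$var_explained[match(components, colnames(object$loadings))], 1)
  ggplot2::ggplot(sc, ggplot2::aes(.data[[components[1]]], .data[[components[2]]])) +
    ggplot2::geom_point() +
    ggplot2::geom_segment(
      data = ld,
      ggplot2::aes(x = 0, y = 0,
                   xend = .data[[components[1]]] * scale_f,
                   yend = .data[[components[2]]] * scale_f),
      colour = "steelblue", alpha = 0.7,
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))
    ) +
    ggplot2::geom_text(
      data = ld,
      ggplot2::aes(x = .data[[components[1]]] * scale_f * 1.08,
                   y = .data[[components[2]]] * scale_f * 1.08,
                   label = .data$variable),
      colour = "steelblue", size = 3
    ) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", components[1], pct[1]),
      y = sprintf("%s (%.1f%%)", components[2], pct[2])
    ) +
    ggplot2::theme_minimal()
}

#' Scatter plot of a phylogenetic regression
#'
#' @param object A `pgls_fit` from [pgls_fit()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.pgls_fit <- function(object, ...) {
  b <- object$coefficients
  ggplot2::ggplot(object$data, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = b[1], slope = b[2], colour = "firebrick") +
    ggplot2::labs(
      x = object$predictor, y = object$response,
      title = sprintf("PGLS: lambda = %.3g, adj. r² = %.3g, p = %.3g",
                      object$lambda, object$adj_r_squared, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Trait trend over divergence time
#'
#' Per-species points with the mean-at-each-divergence-time trend line.
#'
#' @param traits Data frame with the trait and divergence-time columns.
#' @param value Trait column name.
#' @param time Divergence-time column name.
#' @return A ggplot object.
#' @export
plot_divergence_trend <- function(traits, value, time = "divergence_time") {
  trend <- divergence_trend(traits, value, time)
  ggplot2::ggplot(traits, ggplot2::aes(.data[[time]], .data[[value]])) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(
      data = trend, ggplot2::aes(.data$time, .data$mean_value),
      colour = "firebrick"
    ) +
    ggplot2::labs(x = "divergence time (My)", y = value) +
    ggplot2::theme_minimal()
}
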