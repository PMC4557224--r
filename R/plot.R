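# ggplot2 graphics for the package's result types.

#' Plot a scalar field as a raster heat map
#'
#' @param object A [scalar_field].
#' @param ... Unused.
#' @return A ggplot object (row 1 at the top, image orientation).
#' @method autoplot scalar_field
#' @export
autoplot.scalar_field <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "density") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column (px)", y = "row (px)") +
    ggplot2::theme_minimal()
}

#' Scatter plot of paired field densities
#'
#' The classic colocalization view: density of field A against density of
#' field B per pixel. Point clouds hugging the diagonal indicate
#' colocalized objects; forked clouds indicate separated objects.
#'
#' @param object A [pair_fields()] result.
#' @param alpha Point transparency.
#' @param max_points Subsample cap for plotting speed.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot paired_samples
#' @export
autoplot.paired_samples <- function(object, alpha = 0.1, max_points = 50000, ...) {
  df <- as_tibble(object)
  if (nrow(df) > max_points)
    df <- dplyr::slice_sample(df, n = max_points)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b)) +
    ggplot2::geom_point(alpha = alpha, size = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::coord_fixed(xlim = c(0, 100), ylim = c(0, 100)) +
    ggplot2::labs(x = "field A density", y = "field B density") +
    ggplot2::theme_minimal()
}

#' Divergence heat map with sink centroids
#'
#' @param object A [divergence_sinks()] report.
#' @param ... Unused.
#' @return A ggplot object; sink centroids are marked with crosses.
#' @method autoplot sink_report
#' @export
autoplot.sink_report <- function(object, ...) {
  div <- object$divergence
  df <- tibble(
    row = rep(seq_len(nrow(div)), times = ncol(div)),
    col = rep(seq_len(ncol(div)), each = nrow(div)),
    divergence = as.numeric(div)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$divergence)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "#313695", mid = "white",
                                  high = "#a50026", midpoint = 0) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column (px)", y = "row (px)") +
    ggplot2::theme_minimal()
  if (object$n_sinks > 0)
    p <- p + ggplot2::geom_point(
      data = object$sink_centroids,
      ggplot2::aes(x = .data$col, y = .data$row), inherit.aes = FALSE,
      shape = 4, size = 3, stroke = 1.2, colour = "black")
  p
}

#' Intersection-distance profile plot
#'
#' @param profile Tibble from [intersection_distance_profile()].
#' @return A ggplot object.
#' @export
plot_intersection_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$distance,
                                        y = .data$intersection)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "point separation (px)", y = "histogram intersection") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
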