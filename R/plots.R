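#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot sensitivity maps as planar projections
#'
#' Heatmaps of a map projection (default XZ: summed over Y), facetted by
#' method and moment, with depth increasing downwards — the layout in which
#' banana-shaped sensitivity profiles are conventionally displayed.
#'
#' @param object A `sensitivity_maps` tibble.
#' @param plane `"xz"`, `"yz"` or `"xy"`, see [project_maps()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sensitivity_maps <- function(object, plane = "xz", ...) {
  proj <- project_maps(object, plane)
  ax <- names(proj)[1:2]
  pl <- ggplot2::ggplot(proj, ggplot2::aes(
    x = .data[[ax[1]]], y = .data[[ax[2]]], fill = .data$value
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$moment), cols = ggplot2::vars(.data$method),
      scales = "free"
    ) +
    ggplot2::labs(x = paste(ax[1]), y = paste(ax[2]), fill = "ΔM") +
    ggplot2::theme_minimal()
  if (ax[2] == "z_mm") pl <- pl + ggplot2::scale_y_reverse()
  pl
}

#' @rdname autoplot.sensitivity_maps
#' @export
plot_maps <- function(object, plane = "xz", ...) autoplot(object, plane = plane, ...)

#' Plot normalized depth-related sensitivity profiles
#'
#' @param object A [depth_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.depth_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(
    x = .data$z_mm, y = .data$normalized, colour = .data$method
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$moment)) +
    ggplot2::labs(x = "depth Z (mm)", y = "normalized layer sensitivity") +
    ggplot2::theme_minimal()
}

#' Plot depth-selectivity curves
#'
#' @param object A [depth_selectivity()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.selectivity_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(
    x = .data$z_start_mm, y = .data$S, colour = .data$method
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$moment), scales = "free_y") +
    ggplot2::labs(x = "deep-layer start depth Z (mm)", y = "depth selectivity S") +
    ggplot2::theme_minimal()
}

#' Plot the depth-selectivity / CNR trade-off
#'
#' Scatter of |CNR| against |S| per method and moment; iso-performance
#' contours (constant |S x CNR|) are hyperbolas on this plane, so points
#' further from the origin along both axes perform better.
#'
#' @param object An [overall_performance()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.performance_score <- function(object, ...) {
  tb <- tibble::as_tibble(object)
  ggplot2::ggplot(tb, ggplot2::aes(
    x = abs(.data$S), y = abs(.data$CNR),
    colour = .data$method, shape = .data$moment
  )) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.3g", .data$magnitude)),
      vjust = -1, size = 3, show.legend = FALSE
    ) +
    ggplot2::labs(x = "|depth selectivity|", y = "|CNR|") +
    ggplot2::theme_minimal()
}
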