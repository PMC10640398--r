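#' Spatial label map
#'
#' Tile/point map of labels over spot coordinates. Works for grid (`row`,
#' `col`) and Euclidean (`x`, `y`) coordinates; rows are drawn top-down so
#' band 1 appears at the top, matching the layered-tissue convention.
#'
#' @param coords Tibble with `spot_id` and `row`,`col` or `x`,`y`.
#' @param labels Vector of labels, one per coordinate row.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_label_map <- function(coords, labels, title = NULL) {
  df <- tibble::as_tibble(coords)
  df$label <- factor(labels)
  if (all(c("row", "col") %in% names(df))) {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                          fill = .data$label)) +
      ggplot2::geom_tile() +
      ggplot2::scale_y_reverse() +
      ggplot2::coord_equal() +
      ggplot2::labs(fill = "type")
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                          colour = .data$label)) +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::coord_equal() +
      ggplot2::labs(colour = "type")
  }
  p + ggplot2::theme_minimal() + ggplot2::ggtitle(title)
}

#' @describeIn plot_label_map Map of a fit's assigned types; pass the
#'   coordinates used to build the graph.
#' @param object A `span_fit` or `span_sim`.
#' @param coords Coordinates tibble (required for `span_fit`).
#' @param ... Unused.
#' @method autoplot span_fit
#' @export
autoplot.span_fit <- function(object, coords, ...) {
  plot_label_map(coords, object$type, title = "assigned types")
}

#' @describeIn plot_label_map Map of a simulated dataset's true types.
#' @method autoplot span_sim
#' @export
autoplot.span_sim <- function(object, ...) {
  plot_label_map(object$coords,
                 type_labels(object$config$K)[object$z_true],
                 title = "simulated true types")
}

#' @describeIn plot_label_map Convergence history of a fit: label-change
#'   fraction per ICM iteration.
#' @param fit A `span_fit`.
#' @export
plot_convergence <- function(fit) {
  ggplot2::ggplot(fit$history,
                  ggplot2::aes(x = .data$iter, y = .data$changed_fraction)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "ICM iteration", y = "fraction of labels changed") +
    ggplot2::theme_minimal()
}
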