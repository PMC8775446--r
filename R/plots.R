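# ggplot2 visualisations for the main result types.

#' Plot a spatial event map
#'
#' Heat map of smoothed, normalized event counts over track bins, one row
#' per cell, cells ordered by the angular position of their map peak (the
#' standard place-field "sequence" plot).
#'
#' @param map Tibble from [spatial_event_map()].
#' @return A ggplot object.
#' @export
plot_event_map <- function(map) {
  peak <- summarise(group_by(map, .data$cell_id),
    peak_bin = .data$bin[which.max(.data$smoothed)], .groups = "drop"
  )
  ord <- peak$cell_id[order(peak$peak_bin)]
  map <- mutate(map, cell_id = factor(.data$cell_id, levels = ord))
  ggplot2::ggplot(map, ggplot2::aes(.data$bin, .data$cell_id,
    fill = .data$smoothed
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "normalized\nevent rate") +
    ggplot2::labs(x = "track bin", y = "cell (sorted by peak)") +
    ggplot2::theme_minimal()
}

#' Plot per-visit selectivity scores
#'
#' Raster of smoothed selectivity scores by visit index for each field, with
#' the relevance threshold applied as the colour midpoint.
#'
#' @param scores Tibble from [smooth_selectivity()].
#' @param threshold Relevance threshold used for the colour scale midpoint.
#' @return A ggplot object.
#' @export
plot_selectivity <- function(scores, threshold = 0.5) {
  scores <- mutate(scores,
    field = paste(.data$cell_id, .data$field_id, sep = "/")
  )
  ggplot2::ggplot(scores, ggplot2::aes(.data$visit, .data$field,
    fill = .data$smoothed
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "white", mid = "grey80", high = "firebrick",
      midpoint = threshold, na.value = "grey95", name = "smoothed\nscore"
    ) +
    ggplot2::labs(x = "visit", y = "place field") +
    ggplot2::theme_minimal()
}

#' @describeIn laplacian_eigenmaps Scatter plot of the first two embedding
#'   coordinates, coloured by time or by the true angular position when a
#'   `positions` tibble is supplied.
#' @param object A `pf_embedding`.
#' @param positions Optional [window_positions()] tibble for angle colouring.
#' @export
autoplot.pf_embedding <- function(object, positions = NULL, ...) {
  df <- tidy(object)
  if (!is.null(positions)) {
    df$angle <- positions$theta[object$kept_nodes]
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2,
      colour = .data$angle
    )) +
      ggplot2::scale_colour_gradientn(
        colours = grDevices::hcl.colors(12, "Spectral"),
        name = "track angle"
      )
  } else if (!is.null(df$t)) {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2,
      colour = .data$t
    )) +
      ggplot2::scale_colour_viridis_c(name = "time (s)")
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2))
  }
  p + ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "embedding dim 1", y = "embedding dim 2",
      title = paste(object$method, "embedding")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a sliding residual-variance series
#'
#' @param srv Tibble from [sliding_rv()].
#' @return A ggplot object.
#' @export
plot_sliding_rv <- function(srv) {
  ggplot2::ggplot(
    filter(srv, .data$ok),
    ggplot2::aes(.data$t_center, .data$rv)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "window centre (s)", y = "residual variance") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
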