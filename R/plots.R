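#' Heatmap of the weekly intensity matrix
#'
#' Regions (rows, north to south when ordered by latitude) against ISO
#' weeks, filled by mean post probability — the standard display for
#' comparing season timing across a latitudinal gradient.
#'
#' @param weekly Output of [weekly_matrix()].
#' @return A ggplot object.
#' @export
plot_weekly_matrix <- function(weekly) {
  long <- attr(weekly, "long")
  long$region_id <- factor(long$region_id, levels = rev(weekly$region_id))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$week, y = .data$region_id, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "post\nprobability", na.value = "grey90") +
    ggplot2::labs(x = "ISO week", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Choropleth of regional intensity Z-scores
#'
#' @param intensity_tbl Tibble with `region_id` and a Z-score column.
#' @param regions Region tibble with polygon geometry.
#' @param fill Name of the Z-score column to map (default `"annual_z"`).
#' @return A ggplot object.
#' @export
plot_intensity_map <- function(intensity_tbl, regions, fill = "annual_z") {
  polys <- purrr::map2(
    regions$region_id, regions$geometry,
    ~ tibble(region_id = .x, lon = .y[, 1], lat = .y[, 2])
  ) |> dplyr::bind_rows()
  polys <- dplyr::left_join(polys, intensity_tbl, by = "region_id")
  ggplot2::ggplot(polys, ggplot2::aes(
    x = .data$lon, y = .data$lat,
    group = .data$region_id, fill = .data[[fill]]
  )) +
    ggplot2::geom_polygon(color = "white", linewidth = 0.3) +
    ggplot2::scale_fill_gradient2(name = "Z-score", low = "#2166ac",
                                  mid = "#f7f7f7", high = "#b2182b") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @rdname plot_weekly_matrix
#' @param object An `aw_intensity` object.
#' @param ... Unused.
#' @export
autoplot.aw_intensity <- function(object, ...) {
  plot_weekly_matrix(object$weekly)
}

#' Raw vs. smoothed stream comparison for one region
#'
#' @param series Long surveillance tibble.
#' @param region One region id.
#' @param streams Streams to show.
#' @return A ggplot object.
#' @export
plot_region_streams <- function(series, region,
                                streams = c("ed_count", "post_probability")) {
  df <- series |>
    dplyr::filter(.data$region_id == region, .data$stream %in% streams)
  sm <- rolling_mean_7d(df)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$date, y = .data$value)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::geom_line(data = sm, color = "#b2182b") +
    ggplot2::facet_wrap(~stream, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = NULL, y = NULL, title = region) +
    ggplot2::theme_minimal()
}
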