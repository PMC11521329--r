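#' Annualized allergy-intensity Z-scores across regions
#'
#' Each region's mean daily post probability over the full window is
#' standardized across regions (sample sd), so a positive Z marks a region
#' with relatively high allergy intensity. Z-scores compare regions, not
#' years: the vector across regions has mean 0 and sd 1 by construction.
#'
#' @param series Long surveillance tibble.
#' @param stream Stream to summarize (default `post_probability`).
#' @return Tibble: `region_id`, `mean_value`, `annual_z`.
#' @export
annual_intensity_z <- function(series, stream = "post_probability") {
  check_series(series)
  means <- series |>
    dplyr::filter(.data$stream == !!stream) |>
    dplyr::group_by(.data$region_id) |>
    dplyr::summarise(mean_value = mean(.data$value, na.rm = TRUE), .groups = "drop")
  if (nrow(means) < 2) abort("Z-scores need at least 2 regions.")
  s <- sd(means$mean_value)
  if (!is.finite(s) || s == 0) abort("zero cross-region variance: Z-scores undefined.")
  dplyr::mutate(means, annual_z = (.data$mean_value - mean(.data$mean_value)) / s)
}

#' Seasonal allergy-intensity Z-scores across regions
#'
#' Per season, each region's mean daily post probability over all days of
#' that season (pooled across years) is standardized across regions within
#' the season.
#'
#' @inheritParams annual_intensity_z
#' @param windows An [season_windows()] object.
#' @return Tibble: `region_id`, `season`, `mean_value`, `seasonal_z`.
#' @export
seasonal_intensity_z <- function(series, windows = season_windows(),
                                 stream = "post_probability") {
  check_series(series)
  df <- series |>
    dplyr::filter(.data$stream == !!stream) |>
    dplyr::mutate(season = season_of_month(month_of(.data$date), windows)) |>
    dplyr::group_by(.data$region_id, .data$season) |>
    dplyr::summarise(mean_value = mean(.data$value, na.rm = TRUE), .groups = "drop")
  if (length(unique(df$region_id)) < 2) abort("Z-scores need at least 2 regions.")
  df |>
    dplyr::group_by(.data$season) |>
    dplyr::mutate(seasonal_z = {
      s <- sd(.data$mean_value)
      if (!is.finite(s) || s == 0) abort("zero cross-region variance in a season: Z-scores undefined.")
      (.data$mean_value - mean(.data$mean_value)) / s
    }) |>
    dplyr::ungroup()
}

#' Peak date of the allergy season
#'
#' Day of year at which the (7-day-smoothed) series attains its maximum
#' within a season window of a given year; ties break to the earliest day.
#' Winter windows span the year boundary: winter of year Y runs November Y
#' through February Y+1. An all-missing window is reported explicitly with
#' `status = "undefined"`.
#'
#' @param series Long surveillance tibble (smoothed upstream).
#' @param season Season name in `windows`.
#' @param windows An [season_windows()] object.
#' @param stream Stream to scan.
#' @return Tibble: `region_id`, `season`, `season_year`, `peak_date`,
#'   `peak_doy`, `status`.
#' @export
peak_date <- function(series, season = "spring", windows = season_windows(),
                      stream = "post_probability") {
  check_series(series)
  if (!season %in% names(windows)) abort("unknown season name.")
  w <- windows[[season]]
  df <- series |>
    dplyr::filter(.data$stream == !!stream) |>
    dplyr::mutate(month = month_of(.data$date), year = year_of(.data$date)) |>
    dplyr::filter(.data$month %in% w)
  wraps <- any(w == 12) && any(w == 1)
  df <- dplyr::mutate(
    df,
    season_year = ifelse(wraps & .data$month < w[1], .data$year - 1L, .data$year)
  )
  df |>
    dplyr::group_by(.data$region_id, .data$season_year) |>
    dplyr::summarise(
      peak_date = if (all(is.na(.data$value))) as.Date(NA) else {
        .data$date[which.max(.data$value)]   # which.max: earliest tie wins
      },
      status = if (all(is.na(.data$value))) "undefined" else "ok",
      .groups = "drop"
    ) |>
    dplyr::mutate(
      season = season,
      peak_doy = day_of_year(.data$peak_date)
    ) |>
    dplyr::select(
      "region_id", "season", "season_year", "peak_date", "peak_doy", "status"
    )
}

#' Weekly intensity matrix
#'
#' ISO-week means of the raw post probability per region, rows ordered by
#' descending region-centroid latitude (north to south) when a region table
#' is supplied.
#'
#' @param series Long surveillance tibble (raw, unsmoothed).
#' @param regions Optional region tibble supplying `lat` for row ordering.
#' @param stream Stream to summarize.
#' @return A wide tibble (`region_id` then one column per ISO week), with
#'   the numeric matrix in attribute `"matrix"` and the long form in
#'   attribute `"long"`.
#' @export
weekly_matrix <- function(series, regions = NULL, stream = "post_probability") {
  check_series(series)
  long <- series |>
    dplyr::filter(.data$stream == !!stream) |>
    dplyr::mutate(week = iso_week(.data$date)) |>
    dplyr::group_by(.data$region_id, .data$week) |>
    dplyr::summarise(
      value = if (all(is.na(.data$value))) NA_real_ else mean(.data$value, na.rm = TRUE),
      .groups = "drop"
    )
  if (!is.null(regions)) {
    ord <- regions$region_id[order(-regions$lat)]
    long$region_id <- factor(long$region_id, levels = intersect(ord, unique(long$region_id)))
  } else {
    long$region_id <- factor(long$region_id)
  }
  wide <- long |>
    dplyr::arrange(.data$region_id, .data$week) |>
    tidyr::pivot_wider(names_from = "week", values_from = "value") |>
    dplyr::mutate(region_id = as.character(.data$region_id))
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$region_id
  long$region_id <- as.character(long$region_id)
  attr(wide, "matrix") <- m
  attr(wide, "long") <- long
  wide
}

#' Full intensity-mapping stage
#'
#' Convenience wrapper producing annual Z-scores, per-season Z-scores, peak
#' dates for the dominant (spring) and secondary (fall) seasons, and the
#' weekly intensity matrix in one object. Peak detection runs on the
#' 7-day-smoothed series to match the denoising; the weekly matrix uses the
#' raw probabilities.
#'
#' @param series Long surveillance tibble containing a `post_probability`
#'   stream (raw).
#' @param regions Region tibble (for row ordering of the weekly matrix).
#' @param windows An [season_windows()] object.
#' @param peak_seasons Seasons for which to report peak dates.
#' @return A list of class `aw_intensity` with elements `annual`,
#'   `seasonal`, `peaks`, `weekly`.
#' @export
map_intensity <- function(series, regions = NULL, windows = season_windows(),
                          peak_seasons = c("spring", "fall")) {
  smoothed <- rolling_mean_7d(series)
  peaks <- purrr::map(
    peak_seasons,
    ~ peak_date(smoothed, season = .x, windows = windows)
  ) |> dplyr::bind_rows()
  structure(
    list(
      annual = annual_intensity_z(series),
      seasonal = seasonal_intensity_z(series, windows),
      peaks = peaks,
      weekly = weekly_matrix(series, regions)
    ),
    class = "aw_intensity"
  )
}

#' @export
print.aw_intensity <- function(x, ...) {
  cat("Allergy-intensity mapping over", nrow(x$annual), "regions\n")
  cat("  annual Z-score range:",
      sprintf("%.2f .. %.2f", min(x$annual$annual_z), max(x$annual$annual_z)), "\n")
  cat("  seasons:", paste(unique(x$seasonal$season), collapse = ", "), "\n")
  invisible(x)
}
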