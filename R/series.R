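#' Aggregate timestamped events into region-day counts
#'
#' Bins events (assigned posts or coded visits) by UTC calendar date and
#' region over a configured date range. Every region-day in the range gets an
#' explicit count, zero where no events fell; events outside the range or
#' without a region assignment are excluded and counted in the `discard_log`
#' attribute so that totals are conserved.
#'
#' @param events Tibble with a `timestamp` (or `date`) column and a region
#'   id column (`assigned_region` or `region_id`).
#' @param regions Region tibble fixing the set of regions.
#' @param stream Name for the output stream.
#' @param date_range Length-2 `Date` vector; defaults to the event span.
#' @return A long surveillance tibble with a `discard_log` attribute.
#' @export
aggregate_daily <- function(events, regions, stream = "allergy_posts",
                            date_range = NULL) {
  rid_col <- if ("assigned_region" %in% names(events)) "assigned_region" else "region_id"
  if (!rid_col %in% names(events)) abort("`events` must carry a region assignment.")
  ev_date <- if ("timestamp" %in% names(events)) {
    as.Date(events$timestamp, tz = "UTC")
  } else if ("date" %in% names(events)) {
    as.Date(events$date)
  } else {
    abort("`events` must have a `timestamp` or `date` column.")
  }
  if (is.null(date_range)) {
    date_range <- range(ev_date, na.rm = TRUE)
  }
  date_range <- as.Date(date_range)
  dates <- seq(date_range[1], date_range[2], by = "day")

  rid <- events[[rid_col]]
  in_range <- !is.na(ev_date) & ev_date >= date_range[1] & ev_date <= date_range[2]
  assigned <- !is.na(rid) & rid %in% regions$region_id
  keep <- in_range & assigned
  n_drop <- sum(!keep)

  counted <- tibble(region_id = rid[keep], date = ev_date[keep]) |>
    dplyr::count(.data$region_id, .data$date, name = "value")
  grid <- tidyr::expand_grid(region_id = regions$region_id, date = dates)
  out <- dplyr::left_join(grid, counted, by = c("region_id", "date")) |>
    dplyr::mutate(
      stream = stream,
      value = ifelse(is.na(.data$value), 0, as.numeric(.data$value))
    ) |>
    dplyr::select(dplyr::all_of(series_cols))
  attr(out, "discard_log") <- tibble(
    stage = "aggregate_daily",
    n_in = nrow(events),
    n_out = nrow(events) - n_drop,
    n_discarded = n_drop
  )
  out
}

#' Daily probability of an allergy-relevant post
#'
#' Divides the allergy-relevant post count by the total post count per
#' region-day, converting raw volume into the probability that a post made
#' that day is allergy-related. Days with zero total posts yield a missing
#' value, not zero.
#'
#' @param series Long tibble containing both `allergy_posts` and
#'   `total_posts` streams.
#' @return A long tibble with stream `post_probability`.
#' @export
post_probability <- function(series) {
  check_series(series)
  wide <- series |>
    dplyr::filter(.data$stream %in% c("allergy_posts", "total_posts")) |>
    tidyr::pivot_wider(names_from = "stream", values_from = "value")
  if (!all(c("allergy_posts", "total_posts") %in% names(wide))) {
    abort("series must contain both `allergy_posts` and `total_posts` streams.")
  }
  bad <- !is.na(wide$allergy_posts) & !is.na(wide$total_posts) &
    wide$allergy_posts > wide$total_posts
  if (any(bad)) abort("allergy_posts exceeds total_posts on some days.")
  wide |>
    dplyr::mutate(
      stream = "post_probability",
      value = ifelse(.data$total_posts > 0, .data$allergy_posts / .data$total_posts, NA_real_)
    ) |>
    dplyr::select(dplyr::all_of(series_cols))
}

#' Centered 7-day moving average
#'
#' The denoising low-pass filter: a centered 7-day window (+/- 3 days)
#' removes high-frequency noise and eliminates periodic day-of-week effects
#' exactly (an interior window covers each weekday once). A window value is
#' the mean of its non-missing entries when at least 4 of the 7 are present
#' (this rule also governs the 4-6-day windows at the series edges);
#' otherwise the smoothed value is missing. Counts are never interpolated.
#'
#' @param series Long surveillance tibble of daily values.
#' @return The smoothed tibble (same shape).
#' @export
rolling_mean_7d <- function(series) {
  check_series(series)
  smooth_one <- function(x) {
    zoo::rollapply(
      x, 7,
      function(w) if (sum(!is.na(w)) >= 4) mean(w, na.rm = TRUE) else NA_real_,
      align = "center", partial = TRUE
    )
  }
  series |>
    dplyr::group_by(.data$region_id, .data$stream) |>
    dplyr::arrange(.data$date, .by_group = TRUE) |>
    dplyr::mutate(value = smooth_one(.data$value)) |>
    dplyr::ungroup()
}

#' Rates per 100,000 population
#'
#' @param series Long surveillance tibble (count streams).
#' @param regions Region tibble supplying populations (all > 0).
#' @param per Denominator population (default 100,000).
#' @return The tibble with values scaled to events per `per` people.
#' @export
per_capita <- function(series, regions, per = 100000) {
  check_series(series)
  pops <- setNames(regions$population, regions$region_id)
  if (any(pops[unique(series$region_id)] <= 0, na.rm = TRUE)) {
    abort("populations must be positive for per-capita scaling.")
  }
  if (any(!series$region_id %in% names(pops))) {
    abort("series contains regions absent from `regions`.")
  }
  dplyr::mutate(series, value = as.numeric(.data$value * per / pops[.data$region_id]))
}

#' Mask date ranges from a series
#'
#' Sets values inside the given closed date intervals to missing while
#' keeping the date index intact — used e.g. to drop the pandemic year 2020,
#' when altered patterns of hospital attendance make ED data unusable.
#'
#' @param series Long surveillance tibble.
#' @param ranges A list of length-2 date vectors (or a two-column data frame
#'   `start`/`end`) of closed intervals. An empty list is the identity.
#' @return The masked tibble (same shape).
#' @export
exclude_date_range <- function(series, ranges) {
  check_series(series)
  if (is.data.frame(ranges)) {
    ranges <- purrr::map2(ranges$start, ranges$end, c)
  }
  if (!length(ranges)) return(series)
  mask <- rep(FALSE, nrow(series))
  for (rg in ranges) {
    rg <- as.Date(rg)
    if (length(rg) != 2 || any(is.na(rg)) || rg[1] > rg[2]) {
      abort("malformed date range: need start <= end, both valid dates.")
    }
    mask <- mask | (series$date >= rg[1] & series$date <= rg[2])
  }
  series$value[mask] <- NA_real_
  series
}

#' Region data-sufficiency filter
#'
#' Applies the inclusion rules for the validation battery: a region is
#' retained iff its population is at least `min_population` AND its total
#' allergy-coded ED encounters per 100,000 people and total allergy-relevant
#' posts per 100,000 people over the analysis window both reach their
#' thresholds. Values exactly at a threshold pass ("fewer than" excludes).
#'
#' @param series Long surveillance tibble containing `ed_count` and
#'   `allergy_posts` streams (raw counts over the analysis window).
#' @param regions Region tibble with populations.
#' @param thresholds An [quality_thresholds()] object.
#' @return A report tibble with one row per region: totals, per-100k rates,
#'   one pass flag per criterion, and `included`. The included ids are
#'   `report$region_id[report$included]`.
#' @export
quality_filter <- function(series, regions, thresholds = quality_thresholds()) {
  check_series(series)
  stopifnot(inherits(thresholds, "aw_thresholds"))
  totals <- series |>
    dplyr::filter(.data$stream %in% c("ed_count", "allergy_posts")) |>
    dplyr::group_by(.data$region_id, .data$stream) |>
    dplyr::summarise(total = sum(.data$value, na.rm = TRUE), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "stream", values_from = "total")
  if (!all(c("ed_count", "allergy_posts") %in% names(totals))) {
    abort("quality_filter needs `ed_count` and `allergy_posts` streams.")
  }
  report <- regions |>
    dplyr::select("region_id", "population") |>
    dplyr::left_join(totals, by = "region_id") |>
    dplyr::mutate(
      ed_total = dplyr::coalesce(.data$ed_count, 0),
      posts_total = dplyr::coalesce(.data$allergy_posts, 0),
      ed_per_100k = .data$ed_total * 1e5 / .data$population,
      posts_per_100k = .data$posts_total * 1e5 / .data$population,
      pass_population = .data$population >= thresholds$min_population,
      pass_ed = .data$ed_per_100k >= thresholds$min_ed_per_100k,
      pass_posts = .data$posts_per_100k >= thresholds$min_posts_per_100k,
      included = .data$pass_population & .data$pass_ed & .data$pass_posts
    ) |>
    dplyr::select(
      "region_id", "population", "ed_per_100k", "posts_per_100k",
      "pass_population", "pass_ed", "pass_posts", "included"
    )
  report
}

#' Pointwise mean of replicate series
#'
#' Averages noisy replicates of the same stream (see
#' [resample_series_replicates()]) back into one series: per region-day, the
#' mean over non-missing replicate values.
#'
#' @param replicates Tibble with a `replicate` column, or a list of series
#'   tibbles sharing dates.
#' @return A long surveillance tibble without the `replicate` column.
#' @export
average_replicates <- function(replicates) {
  if (is.data.frame(replicates)) {
    if (!nrow(replicates)) abort("no replicates supplied.")
  } else {
    if (!length(replicates)) abort("no replicates supplied.")
    replicates <- dplyr::bind_rows(
      purrr::imap(replicates, ~ dplyr::mutate(.x, replicate = .y))
    )
  }
  check_series(replicates)
  replicates |>
    dplyr::group_by(.data$region_id, .data$date, .data$stream) |>
    dplyr::summarise(
      value = if (all(is.na(.data$value))) NA_real_ else mean(.data$value, na.rm = TRUE),
      .groups = "drop"
    )
}
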