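#' Centroid of a geotag bounding box
#'
#' Social platforms attach a rectangular place extent to geotagged posts; the
#' arithmetic midpoint of the box corners localizes the post for county
#' assignment. Degenerate (point) boxes are allowed.
#'
#' @param min_lon,min_lat,max_lon,max_lat Numeric vectors (recycled to a
#'   common length) describing the boxes; alternatively `min_lon` may be a
#'   data frame carrying all four columns.
#' @return A tibble with columns `lon`, `lat`.
#' @export
bbox_centroid <- function(min_lon, min_lat = NULL, max_lon = NULL, max_lat = NULL) {
  if (is.data.frame(min_lon)) {
    df <- min_lon
    min_lon <- df$min_lon; min_lat <- df$min_lat
    max_lon <- df$max_lon; max_lat <- df$max_lat
  }
  coords <- cbind(min_lon, min_lat, max_lon, max_lat)
  if (any(!is.finite(coords))) abort("bounding boxes contain NaN/Inf coordinates.")
  if (any(min_lon > max_lon) || any(min_lat > max_lat)) {
    abort("invalid bounding box: min corner exceeds max corner.")
  }
  tibble(lon = (min_lon + max_lon) / 2, lat = (min_lat + max_lat) / 2)
}

# Even-odd (ray casting) point-in-polygon on one ring, vectorized over
# points: loops over edges, not points. Returns "in"/"out"/"edge" per point.
# Planar lon/lat geometry: adequate at county scale.
point_ring_position <- function(px, py, ring) {
  n <- nrow(ring)
  if (n < 3) abort("polygon ring must have at least 3 vertices.")
  # drop duplicated closing vertex if present
  if (ring[1, 1] == ring[n, 1] && ring[1, 2] == ring[n, 2]) {
    ring <- ring[-n, , drop = FALSE]
    n <- n - 1L
  }
  inside <- rep(FALSE, length(px))
  edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    on_seg <- (px - xi) * (yj - yi) == (py - yi) * (xj - xi) &
      px >= min(xi, xj) & px <= max(xi, xj) &
      py >= min(yi, yj) & py <= max(yi, yj)
    edge <- edge | on_seg
    crosses <- (yi > py) != (yj > py)
    if (any(crosses)) {
      xint <- xi + (py - yi) / (yj - yi) * (xj - xi)
      inside <- xor(inside, crosses & px < xint)
    }
    j <- i
  }
  out <- ifelse(edge, "edge", ifelse(inside, "in", "out"))
  out
}

#' Assign a point to the region containing it
#'
#' Point-in-polygon by the even-odd (ray casting) rule. Regions must
#' partition the plane region they cover: a point strictly inside more than
#' one polygon raises an ambiguity error. A point lying exactly on a shared
#' edge is assigned deterministically to the lexicographically smallest
#' containing `region_id`. A point in no region returns `NA`.
#'
#' @param lon,lat Point coordinates (vectors allowed, recycled).
#' @param regions A region tibble (see [generate_regions()]).
#' @return Character vector of region ids (`NA` where unassigned).
#' @export
assign_point_to_region <- function(lon, lat, regions) {
  if (!nrow(regions)) abort("`regions` must be non-empty.")
  n <- max(length(lon), length(lat))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  if (any(!is.finite(lon)) || any(!is.finite(lat))) {
    abort("point coordinates contain NaN/Inf.")
  }
  # position of every point w.r.t. every region, edge-vectorized
  pos <- vapply(
    regions$geometry,
    function(ring) point_ring_position(lon, lat, ring),
    character(n)
  )
  pos <- matrix(pos, nrow = n)
  n_strict <- rowSums(pos == "in")
  if (any(n_strict > 1)) {
    abort("ambiguous point: strictly inside multiple regions (regions must partition).")
  }
  out <- rep(NA_character_, n)
  # region ids sorted so that the first containing match is the
  # lexicographically smallest (the deterministic edge tie-break)
  ord <- order(regions$region_id)
  for (ri in ord) {
    hit <- is.na(out) & pos[, ri] == "in"
    out[hit] <- regions$region_id[ri]
  }
  for (ri in ord) {
    hit <- is.na(out) & pos[, ri] == "edge"
    out[hit] <- regions$region_id[ri]
  }
  out
}

#' Assign posts to regions via their bounding-box centroids
#'
#' Computes each post's bounding-box centroid and assigns it to the
#' containing region. Posts whose centroid falls in no region are retained
#' with `region_id = NA` and counted in the `discard_log` attribute, never
#' dropped silently.
#'
#' @param posts A post tibble with `min_lon`, `min_lat`, `max_lon`, `max_lat`.
#' @param regions A region tibble.
#' @return `posts` with an `assigned_region` column and a `discard_log`
#'   attribute.
#' @export
assign_posts_to_regions <- function(posts, regions) {
  ctr <- bbox_centroid(posts)
  posts$assigned_region <- assign_point_to_region(ctr$lon, ctr$lat, regions)
  n_na <- sum(is.na(posts$assigned_region))
  attr(posts, "discard_log") <- tibble(
    stage = "region_assignment",
    n_in = nrow(posts),
    n_out = nrow(posts) - n_na,
    n_discarded = n_na
  )
  posts
}

#' Aggregate region-level series to DMA level
#'
#' Designated market areas (DMAs) are the finest geography of search-trend
#' data and typically span several counties, so county-level streams must be
#' rolled up for comparison: count streams are summed within DMA per day;
#' probability streams are population-weighted means. Dates are unchanged.
#'
#' @param series Long surveillance tibble.
#' @param regions Region tibble supplying `dma_id` and `population`.
#' @return A long tibble keyed by `dma_id` instead of `region_id`.
#' @export
aggregate_regions_to_dma <- function(series, regions) {
  check_series(series)
  known <- c(count_streams, probability_streams)
  bad <- setdiff(unique(series$stream), known)
  if (length(bad)) {
    abort(paste0(
      "cannot aggregate stream(s) of unknown type: ",
      paste(bad, collapse = ", "),
      " (counts are summed, probabilities population-weighted; mixing other types is not defined)."
    ))
  }
  if (!all(series$region_id %in% regions$region_id)) {
    abort("series contains regions absent from `regions`.")
  }
  joined <- dplyr::left_join(
    series,
    regions[, c("region_id", "dma_id", "population")],
    by = "region_id"
  )
  counts <- joined |>
    dplyr::filter(.data$stream %in% count_streams) |>
    dplyr::group_by(.data$dma_id, .data$date, .data$stream) |>
    dplyr::summarise(value = sum(.data$value), .groups = "drop")
  probs <- joined |>
    dplyr::filter(is_probability_stream(.data$stream)) |>
    dplyr::group_by(.data$dma_id, .data$date, .data$stream) |>
    dplyr::summarise(
      value = {
        ok <- !is.na(.data$value)
        if (!any(ok)) NA_real_ else {
          sum(.data$value[ok] * .data$population[ok]) / sum(.data$population[ok])
        }
      },
      .groups = "drop"
    )
  dplyr::bind_rows(counts, probs) |>
    dplyr::arrange(.data$dma_id, .data$stream, .data$date)
}
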