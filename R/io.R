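#' Read and write region tables as GeoJSON
#'
#' Regions are exchanged as a GeoJSON FeatureCollection of single-ring
#' Polygons with properties `region_id`, `name`, `population`, `dma_id`.
#' Polygons with holes (multiple rings) are not supported and raise an
#' explicit error.
#'
#' @param regions A region tibble (see [generate_regions()]).
#' @param path File path.
#' @return `read_regions_geojson()` returns a region tibble;
#'   `write_regions_geojson()` returns `path` invisibly.
#' @export
write_regions_geojson <- function(regions, path) {
  features <- purrr::map(seq_len(nrow(regions)), function(i) {
    ring <- regions$geometry[[i]]
    if (ring[1, 1] != ring[nrow(ring), 1] || ring[1, 2] != ring[nrow(ring), 2]) {
      ring <- rbind(ring, ring[1, ])
    }
    list(
      type = "Feature",
      properties = list(
        region_id = regions$region_id[i],
        name = regions$name[i],
        population = regions$population[i],
        dma_id = regions$dma_id[i]
      ),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)), function(j) unname(ring[j, ])))
      )
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_regions_geojson
#' @export
read_regions_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection")) {
    abort("GeoJSON must be a FeatureCollection.")
  }
  rows <- purrr::map(gj$features, function(f) {
    geom <- f$geometry
    if (!identical(geom$type, "Polygon")) abort("only Polygon geometries are supported.")
    if (length(geom$coordinates) != 1) {
      abort("polygons with holes (multiple rings) are not supported.")
    }
    ring <- do.call(rbind, lapply(geom$coordinates[[1]], function(p) {
      as.numeric(unlist(p))
    }))
    colnames(ring) <- c("lon", "lat")
    props <- f$properties
    for (field in c("region_id", "name", "population", "dma_id")) {
      if (is.null(props[[field]])) {
        abort(paste0("GeoJSON feature missing property '", field, "'."))
      }
    }
    if (props$population <= 0) abort("schema error in 'population': must be > 0.")
    tibble(
      region_id = props$region_id,
      name = props$name,
      population = as.numeric(props$population),
      dma_id = props$dma_id,
      lon = mean(range(ring[, 1])),
      lat = mean(range(ring[, 2])),
      geometry = list(ring)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (anyDuplicated(out$region_id)) abort("schema error in 'region_id': duplicates found.")
  out
}

#' Read and write post records as JSON Lines
#'
#' One JSON object per line: `post_id`, `timestamp` (ISO-8601 UTC), `bbox`
#' (`[min_lon, min_lat, max_lon, max_lat]`), `text`, `label` (may be null),
#' and optionally `region_id`. Schema violations name the offending field.
#'
#' @param posts A post tibble (see [generate_posts()]).
#' @param path File path.
#' @return `read_posts_jsonl()` returns a post tibble;
#'   `write_posts_jsonl()` returns `path` invisibly.
#' @export
write_posts_jsonl <- function(posts, path) {
  has_region <- "region_id" %in% names(posts)
  esc <- function(s) {
    # JSON string escaping for the characters our records can contain
    s <- gsub("\\", "\\\\", s, fixed = TRUE)
    s <- gsub("\"", "\\\"", s, fixed = TRUE)
    s <- gsub("\n", "\\n", s, fixed = TRUE)
    gsub("\t", "\\t", s, fixed = TRUE)
  }
  lines <- sprintf(
    '{"post_id":"%s","timestamp":"%s","bbox":[%.17g,%.17g,%.17g,%.17g],"text":"%s","label":%s%s}',
    esc(posts$post_id),
    format(posts$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    posts$min_lon, posts$min_lat, posts$max_lon, posts$max_lat,
    esc(posts$text),
    ifelse(is.na(posts$label), "null", paste0('"', esc(posts$label), '"')),
    if (has_region) paste0(',"region_id":"', esc(posts$region_id), '"') else ""
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_posts_jsonl
#' @export
read_posts_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  rows <- purrr::map(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    for (field in c("post_id", "timestamp", "bbox", "text")) {
      if (is.null(rec[[field]])) abort(paste0("schema error: missing field '", field, "'."))
    }
    bb <- as.numeric(rec$bbox)
    if (length(bb) != 4 || anyNA(bb)) abort("schema error in 'bbox': need 4 numbers.")
    if (bb[1] > bb[3] || bb[2] > bb[4]) {
      abort("schema error in 'bbox': min corner exceeds max corner.")
    }
    ts <- as.POSIXct(rec$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    if (is.na(ts)) abort("schema error in 'timestamp': not ISO-8601.")
    tibble(
      post_id = rec$post_id,
      timestamp = ts,
      min_lon = bb[1], min_lat = bb[2], max_lon = bb[3], max_lat = bb[4],
      text = rec$text,
      label = rec$label %||% NA_character_,
      region_id = rec$region_id %||% NA_character_
    )
  })
  dplyr::bind_rows(rows)
}

#' Read and write surveillance series as CSV
#'
#' Columns `region_id`, `date` (ISO-8601), `stream`, `value`; missing values
#' are written as empty fields. On read, gaps in the daily date index of any
#' region-stream pair are filled with explicit missing values and a warning
#' is issued.
#'
#' @param series Long surveillance tibble.
#' @param path File path.
#' @return `read_series_csv()` returns a series tibble;
#'   `write_series_csv()` returns `path` invisibly.
#' @export
write_series_csv <- function(series, path) {
  check_series(series)
  readr::write_csv(series[, series_cols], path, na = "")
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      region_id = readr::col_character(),
      date = readr::col_date(),
      stream = readr::col_character(),
      value = readr::col_double()
    ),
    na = ""
  )
  filled <- out |>
    dplyr::group_by(.data$region_id, .data$stream) |>
    tidyr::complete(date = seq(min(.data$date), max(.data$date), by = "day")) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(series_cols)) |>
    dplyr::arrange(.data$region_id, .data$stream, .data$date)
  if (nrow(filled) > nrow(out)) {
    warn(sprintf(
      "filled %d date gap(s) with explicit missing values.",
      nrow(filled) - nrow(out)
    ))
  }
  filled
}
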