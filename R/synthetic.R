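#' Generate toy regions tiling a rectangle
#'
#' Builds `n_regions` axis-aligned rectangular "counties" on a grid, each with
#' a population and a DMA (designated market area) group id. Consecutive
#' regions are grouped into DMAs, which partition the regions. Latitude
#' decreases with region index, so the default region order is north to
#' south. The construction is deterministic given the configuration.
#'
#' @param config An [sim_config()] object.
#' @return A tibble with columns `region_id`, `name`, `population`, `dma_id`,
#'   `lon`, `lat` (centroid), and a `geometry` list-column of closed
#'   (lon, lat) rings.
#' @export
generate_regions <- function(config) {
  stopifnot(inherits(config, "aw_sim_config"))
  n <- config$n_regions
  if (any(config$populations <= 0)) {
    abort("invalid config: populations must be positive for region generation.")
  }
  ncol_grid <- ceiling(sqrt(n))
  cell <- 1.0
  lon0 <- -120
  lat0 <- 42
  rows <- (seq_len(n) - 1L) %/% ncol_grid
  cols <- (seq_len(n) - 1L) %% ncol_grid
  dma_size <- ceiling(n / config$n_dma)
  dma_idx <- ((seq_len(n) - 1L) %/% dma_size) + 1L
  geometry <- purrr::map(seq_len(n), function(i) {
    xmin <- lon0 + cols[i] * cell
    ymax <- lat0 - rows[i] * cell
    xmax <- xmin + cell
    ymin <- ymax - cell
    cbind(
      lon = c(xmin, xmax, xmax, xmin, xmin),
      lat = c(ymin, ymin, ymax, ymax, ymin)
    )
  })
  tibble(
    region_id = sprintf("r%02d", seq_len(n)),
    name = sprintf("Region %02d", seq_len(n)),
    population = as.numeric(config$populations),
    dma_id = sprintf("dma%02d", dma_idx),
    lon = purrr::map_dbl(geometry, ~ mean(range(.x[, 1]))),
    lat = purrr::map_dbl(geometry, ~ mean(range(.x[, 2]))),
    geometry = geometry
  )
}

#' Generate the latent aeroallergen process
#'
#' Each region's latent level is the sum of a deterministic annual seasonal
#' component (Gaussian bumps on a circular 365.25-day wrap, so peaks near
#' January 1 behave correctly), a random-walk trend (innovation sd
#' `trend_sd`; one walk per region by default, shared across that region's
#' observation streams; optionally one walk shared across regions with
#' per-region scaling), and a stationary AR(1) anomaly. With `trend_sd = 0`
#' and `anomaly_sd = 0` the series is an exact deterministic annual function.
#'
#' @param config An [sim_config()] object.
#' @return A tibble with columns `region_id`, `date`, `seasonal`, `trend`,
#'   `anomaly`, `value`.
#' @export
generate_latent <- function(config) {
  stopifnot(inherits(config, "aw_sim_config"))
  dates <- config$start_date + seq_len(config$n_days) - 1L
  doy <- day_of_year(dates)
  shared_walk <- NULL
  if (config$share_trend_across_regions) {
    shared_walk <- withr::with_seed(
      substream_seed(config$seed, "trend", "shared"),
      cumsum(rnorm(config$n_days, 0, config$trend_sd))
    )
  }
  out <- purrr::map(seq_len(config$n_regions), function(i) {
    rid <- sprintf("r%02d", i)
    pk <- config$seasonal_peaks[[i]]
    seasonal <- rep(0, config$n_days)
    for (k in seq_len(nrow(pk))) {
      d <- circular_doy_distance(doy, pk$peak_doy[k])
      seasonal <- seasonal + pk$amplitude[k] * exp(-d^2 / (2 * pk$width_days[k]^2))
    }
    trend <- if (config$share_trend_across_regions) {
      config$trend_scale[i] * shared_walk
    } else {
      withr::with_seed(
        substream_seed(config$seed, "trend", rid),
        config$trend_scale[i] * cumsum(rnorm(config$n_days, 0, config$trend_sd))
      )
    }
    anomaly <- withr::with_seed(substream_seed(config$seed, "anomaly", rid), {
      e <- rnorm(config$n_days, 0, config$anomaly_sd)
      as.numeric(stats::filter(e, config$anomaly_ar, method = "recursive"))
    })
    tibble(
      region_id = rid, date = dates,
      seasonal = seasonal, trend = trend, anomaly = anomaly,
      value = seasonal + trend + anomaly
    )
  })
  dplyr::bind_rows(out)
}

# Day-of-week index, Monday = 1, of a Date vector.
dow_index <- function(dates) ((unclass(dates) + 3L) %% 7L) + 1L

# Count-stream draws shared by generate_streams() and generate_posts():
# both must see the exact same Poisson/Binomial realizations.
draw_region_counts <- function(latent_r, config, region_index) {
  rid <- latent_r$region_id[1]
  a <- latent_r$value
  if (any(!is.finite(a))) abort("NaN/Inf in latent series.")
  pop <- config$populations[region_index]
  wk <- config$weekly_pattern[dow_index(latent_r$date)]
  n <- nrow(latent_r)

  # optional independent per-stream random walks (null design: I(1) streams
  # with no shared trend)
  stream_walk <- function(stream) {
    if (config$stream_trend_sd == 0) return(rep(0, n))
    withr::with_seed(
      substream_seed(config$seed, "stream_trend", rid, stream),
      cumsum(rnorm(n, 0, config$stream_trend_sd))
    )
  }
  w_ed <- stream_walk("ed")
  w_posts <- stream_walk("posts")

  ed_rate <- pop / 1e5 *
    pmax(0, config$baseline_ed_rate + config$coupling_ed * a + w_ed) * wk
  ed <- withr::with_seed(
    substream_seed(config$seed, "ed", rid),
    rpois(n, ed_rate)
  )
  total_rate <- pop / 1e5 * config$baseline_post_rate * wk
  total <- withr::with_seed(
    substream_seed(config$seed, "total", rid),
    rpois(n, total_rate)
  )
  frac <- pmin(1, pmax(0, config$relevant_fraction_link(a)))
  if (config$stream_trend_sd > 0) {
    frac <- plogis(qlogis(pmin(1 - 1e-9, pmax(1e-9, frac))) + w_posts)
  }
  allergy <- withr::with_seed(
    substream_seed(config$seed, "allergy", rid),
    rbinom(n, total, frac)
  )
  list(ed = ed, total = total, allergy = allergy)
}

#' Generate the observed surveillance streams
#'
#' Observes the latent process through four coupled streams per region:
#' `ed_count` (Poisson ED visits with rate truncated at zero), `total_posts`
#' (Poisson), `allergy_posts` (Binomial thinning of total posts with a
#' relevance fraction that increases with the latent level), and
#' `search_probability` (a logistic link plus bounded noise, clipped to
#' `[0, 1]`). All count streams carry the configured day-of-week
#' multipliers. Because every stream of a region shares the same latent
#' random-walk trend, the streams are I(1) and pairwise cointegrated by
#' construction whenever `trend_sd > 0` and the couplings are positive.
#'
#' @param latent Output of [generate_latent()] covering all regions.
#' @param config The [sim_config()] used to generate `latent`.
#' @return A long surveillance tibble: `region_id`, `date`, `stream`, `value`.
#' @export
generate_streams <- function(latent, config) {
  stopifnot(inherits(config, "aw_sim_config"))
  if (any(!is.finite(latent$value))) abort("NaN/Inf in latent series.")
  rids <- sprintf("r%02d", seq_len(config$n_regions))
  if (!all(rids %in% unique(latent$region_id))) {
    abort("`latent` must cover every region in `config`.")
  }
  out <- purrr::map(seq_len(config$n_regions), function(i) {
    rid <- rids[i]
    lr <- latent[latent$region_id == rid, , drop = FALSE]
    cts <- draw_region_counts(lr, config, i)
    w_search <- if (config$stream_trend_sd == 0) 0 else withr::with_seed(
      substream_seed(config$seed, "stream_trend", rid, "search"),
      cumsum(rnorm(nrow(lr), 0, config$stream_trend_sd))
    )
    search_mean <- plogis(
      qlogis(config$search_base) + config$coupling_search * lr$value + w_search
    )
    search <- withr::with_seed(
      substream_seed(config$seed, "search", rid),
      pmin(1, pmax(0, search_mean + rnorm(nrow(lr), 0, config$search_noise_sd)))
    )
    dplyr::bind_rows(
      tibble(region_id = rid, date = lr$date, stream = "ed_count", value = as.numeric(cts$ed)),
      tibble(region_id = rid, date = lr$date, stream = "total_posts", value = as.numeric(cts$total)),
      tibble(region_id = rid, date = lr$date, stream = "allergy_posts", value = as.numeric(cts$allergy)),
      tibble(region_id = rid, date = lr$date, stream = "search_probability", value = search)
    )
  })
  dplyr::bind_rows(out)
}

relevant_templates <- c(
  "my %s is acting up again today",
  "ugh %s season is truly terrible right now",
  "cant stop rubbing my eyes this %s is brutal",
  "woke up congested again thanks to %s",
  "took meds this morning but the %s still got me",
  "worst %s flare up of the year i swear"
)

confounder_templates <- c(
  "gluten and %s free expo downtown this weekend",
  "a chicken %s video that is all",
  "our bakery now has a full %s free menu",
  "my dog's %s shampoo finally shipped",
  "interesting lecture on %s immunology published today",
  "the %s free cookbook is on sale again"
)

plain_templates <- c(
  "nice weather out there today",
  "traffic on the highway was wild this morning",
  "great game last night what a finish",
  "coffee with friends downtown later",
  "finally finished that book everyone recommended"
)

#' Generate labeled synthetic posts
#'
#' Emits individual post records whose per-day relevant counts follow exactly
#' the `allergy_posts` process of [generate_streams()] (the same seeded
#' draws). Relevant posts use allergy-symptom sentence templates that always
#' contain a configured keyword. Irrelevant posts come in two flavours:
#' keyword-sharing confounders (e.g. an "allergy free expo") emitted so that
#' they make up `contamination_rate` of keyword-matching posts in
#' expectation, and a smaller stream of plain posts with no keywords. Each
#' post carries a timestamp within the simulated range, a bounding box
#' centred inside its region, and its ground-truth label.
#'
#' @param latent Output of [generate_latent()].
#' @param config The [sim_config()] used to generate `latent`.
#' @return A tibble with columns `post_id`, `timestamp`, `min_lon`,
#'   `min_lat`, `max_lon`, `max_lat`, `text`, `label`, `region_id` (the
#'   generating region, for ground truth).
#' @export
generate_posts <- function(latent, config) {
  stopifnot(inherits(config, "aw_sim_config"))
  if (!length(config$terms$terms)) abort("invalid config: empty keyword list.")
  regions <- generate_regions(config)
  rate <- config$contamination_rate
  out <- purrr::map(seq_len(config$n_regions), function(i) {
    rid <- regions$region_id[i]
    lr <- latent[latent$region_id == rid, , drop = FALSE]
    cts <- draw_region_counts(lr, config, i)
    withr::with_seed(substream_seed(config$seed, "posts", rid), {
      n_rel <- cts$allergy
      n_conf <- rpois(length(n_rel), n_rel * rate / (1 - rate))
      n_plain <- rpois(length(n_rel), n_rel * config$nonkeyword_fraction)
      counts3 <- rbind(n_rel, n_conf, n_plain)   # per day: relevant, confounder, plain
      day_idx <- rep(rep(seq_along(n_rel), each = 3), times = as.vector(counts3))
      label_kind <- rep(
        rep(c("relevant", "confounder", "plain"), length(n_rel)),
        times = as.vector(counts3)
      )
      n_posts <- length(day_idx)
      if (!n_posts) {
        return(tibble(
          post_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
          min_lon = numeric(), min_lat = numeric(), max_lon = numeric(),
          max_lat = numeric(), text = character(), label = character(),
          region_id = character()
        ))
      }
      kw <- sample(config$terms$terms, n_posts, replace = TRUE)
      text <- character(n_posts)
      rel <- label_kind == "relevant"
      conf <- label_kind == "confounder"
      pl <- label_kind == "plain"
      text[rel] <- sprintf(sample(relevant_templates, sum(rel), replace = TRUE), kw[rel])
      text[conf] <- sprintf(sample(confounder_templates, sum(conf), replace = TRUE), kw[conf])
      text[pl] <- sample(plain_templates, sum(pl), replace = TRUE)
      ring <- regions$geometry[[i]]
      xr <- range(ring[, 1]); yr <- range(ring[, 2])
      half <- 0.01
      cx <- runif(n_posts, xr[1] + 0.05, xr[2] - 0.05)
      cy <- runif(n_posts, yr[1] + 0.05, yr[2] - 0.05)
      secs <- runif(n_posts, 0, 86399)
      tibble(
        post_id = NA_character_,
        timestamp = as.POSIXct(lr$date[day_idx], tz = "UTC") + secs,
        min_lon = cx - half, min_lat = cy - half,
        max_lon = cx + half, max_lat = cy + half,
        text = text,
        label = ifelse(rel, "relevant", "irrelevant"),
        region_id = rid
      )
    })
  })
  posts <- dplyr::bind_rows(out)
  posts$post_id <- sprintf("p%08d", seq_len(nrow(posts)))
  posts
}

#' Noisy replicates of a surveillance series
#'
#' Emulates repeated sampling of a search-probability stream (each provider
#' sample sees a different random 10-15% subset of searches) by drawing
#' independent additive-noise replicates of the input, clipped to the valid
#' range of the stream ([0, 1] for probability streams, non-negative for
#' counts). Averaging the replicates back together is [average_replicates()].
#'
#' @param series A long surveillance tibble (see [generate_streams()]).
#' @param n_replicates Number of replicates (>= 1).
#' @param noise_sd Standard deviation of the additive noise (>= 0).
#' @param seed Integer seed.
#' @return The replicated tibble with an integer `replicate` column.
#' @export
resample_series_replicates <- function(series, n_replicates, noise_sd, seed = 1L) {
  check_series(series)
  stopifnot_scalar_number(n_replicates, "n_replicates", min = 1)
  stopifnot_scalar_number(noise_sd, "noise_sd", min = 0)
  lower <- ifelse(series$stream %in% c(count_streams, probability_streams), 0, -Inf)
  upper <- ifelse(is_probability_stream(series$stream), 1, Inf)
  withr::with_seed(as.integer(seed), {
    purrr::map(seq_len(n_replicates), function(r) {
      noisy <- series$value + rnorm(nrow(series), 0, noise_sd)
      dplyr::mutate(series,
        replicate = as.integer(r),
        value = pmin(upper, pmax(lower, noisy))
      )
    })
  }) |>
    dplyr::bind_rows()
}
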