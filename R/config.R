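#' Simulation configuration for coupled surveillance streams
#'
#' Builds the parameter set for the synthetic-data generator. The generator
#' emulates a latent aeroallergen process per region (deterministic annual
#' seasonality plus a shared stochastic trend plus a stationary AR(1)
#' anomaly) observed through four surveillance streams: emergency-department
#' (ED) visit counts, total social-post counts, allergy-relevant post counts,
#' and a bounded search-probability stream. The single stochastic trend is
#' shared across the streams of a region, which makes the observed streams
#' I(1) and pairwise cointegrated by construction.
#'
#' @param n_regions Number of toy regions (counties).
#' @param n_days Length of each daily series. At least 366 days are required
#'   for any annual-seasonality analysis.
#' @param start_date First calendar day (`Date` or ISO-8601 string).
#' @param seasonal_peaks A list with one element per region; each element is a
#'   data frame with columns `peak_doy` (day of year of the seasonal maximum),
#'   `amplitude`, and `width_days` (Gaussian bump width). `NULL` gives every
#'   region a spring peak (day 100) and a weaker fall peak (day 265) with
#'   amplitudes varying across regions.
#' @param trend_sd Per-day standard deviation of the shared random-walk trend
#'   innovations (latent-level units).
#' @param coupling_ed,coupling_posts,coupling_search Non-negative coefficients
#'   linking the latent level to, respectively, the ED visit rate, the
#'   log-odds of a post being allergy-relevant, and the log-odds of the
#'   search-probability stream.
#' @param baseline_ed_rate Baseline ED visits per 100,000 population per day.
#' @param baseline_post_rate Total posts per 100,000 population per day.
#' @param relevant_fraction_base Baseline fraction of posts that are
#'   allergy-relevant when the latent level is zero.
#' @param relevant_fraction_link Monotone function mapping the latent level to
#'   the fraction of posts that are allergy-relevant. Defaults to the
#'   truncated-linear link
#'   `pmin(1, pmax(0, relevant_fraction_base * (1 + coupling_posts * a)))`,
#'   which keeps the post-probability stream linear in the latent level so
#'   the cointegrating relation between streams is itself linear.
#' @param search_base Baseline search probability at latent level zero.
#' @param search_noise_sd Standard deviation of the additive noise on the
#'   search-probability stream (clipped to `[0, 1]`).
#' @param anomaly_sd,anomaly_ar Innovation standard deviation and AR(1)
#'   coefficient of the stationary latent anomaly.
#' @param weekly_pattern Seven non-negative day-of-week multipliers (Monday
#'   first) whose mean must be 1 within 1e-12.
#' @param populations Per-region population counts; `NULL` spreads populations
#'   between 600,000 and 1,500,000.
#' @param n_dma Number of designated market areas (DMAs); consecutive regions
#'   are grouped so DMAs partition the regions.
#' @param contamination_rate Fraction of keyword-matching posts that are
#'   irrelevant confounders (e.g. "allergy free expo").
#' @param nonkeyword_fraction Additional plain irrelevant posts (no keywords)
#'   emitted per relevant post.
#' @param terms Term list used to template post text; see [term_list()].
#' @param stream_trend_sd Innovation standard deviation of an additional
#'   random walk drawn independently for each stream of each region and added
#'   to that stream's linear predictor. Zero (the default) for the coupled
#'   design; positive values give the null design in which every stream is
#'   I(1) but no trend is shared, so no cointegration holds.
#' @param share_trend_across_regions If `TRUE` a single random walk is shared
#'   by all regions (scaled by `trend_scale`); the default gives each region
#'   its own walk, still shared across that region's streams.
#' @param trend_scale Per-region scaling of the shared walk (recycled).
#' @param seed Master integer seed; every generator sub-stream is derived
#'   from it deterministically.
#'
#' @return A list of class `aw_sim_config`.
#' @export
sim_config <- function(n_regions = 8,
                       n_days = 1460,
                       start_date = "2016-01-01",
                       seasonal_peaks = NULL,
                       trend_sd = 0.06,
                       coupling_ed = 0.5,
                       coupling_posts = 0.5,
                       coupling_search = 0.6,
                       baseline_ed_rate = 1.0,
                       baseline_post_rate = 150,
                       relevant_fraction_base = 0.05,
                       relevant_fraction_link = NULL,
                       search_base = 0.10,
                       search_noise_sd = 0.005,
                       anomaly_sd = 0.25,
                       anomaly_ar = 0.8,
                       weekly_pattern = c(0.95, 1.03, 1.06, 1.06, 1.03, 0.95, 0.92),
                       populations = NULL,
                       n_dma = NULL,
                       contamination_rate = 0.2,
                       nonkeyword_fraction = 0.1,
                       terms = default_terms(),
                       stream_trend_sd = 0,
                       share_trend_across_regions = FALSE,
                       trend_scale = 1,
                       seed = 1L) {
  stopifnot_scalar_number(n_regions, "n_regions", min = 1)
  stopifnot_scalar_number(n_days, "n_days", min = 1)
  stopifnot_scalar_number(trend_sd, "trend_sd", min = 0)
  stopifnot_scalar_number(coupling_ed, "coupling_ed", min = 0)
  stopifnot_scalar_number(coupling_posts, "coupling_posts", min = 0)
  stopifnot_scalar_number(coupling_search, "coupling_search", min = 0)
  stopifnot_scalar_number(baseline_ed_rate, "baseline_ed_rate", min = 0)
  stopifnot_scalar_number(baseline_post_rate, "baseline_post_rate", min = 0)
  stopifnot_scalar_number(anomaly_sd, "anomaly_sd", min = 0)
  stopifnot_scalar_number(search_noise_sd, "search_noise_sd", min = 0)
  stopifnot_scalar_number(contamination_rate, "contamination_rate", min = 0)
  stopifnot_scalar_number(stream_trend_sd, "stream_trend_sd", min = 0)
  if (contamination_rate >= 1) abort("`contamination_rate` must be < 1.")
  if (abs(anomaly_ar) >= 1) abort("`anomaly_ar` must lie in (-1, 1).")

  if (length(weekly_pattern) != 7L || any(weekly_pattern < 0)) {
    abort("`weekly_pattern` must be 7 non-negative multipliers.")
  }
  if (abs(mean(weekly_pattern) - 1) > 1e-12) {
    abort("`weekly_pattern` must average 1 within 1e-12; divide by its mean first.")
  }

  n_regions <- as.integer(n_regions)
  n_days <- as.integer(n_days)
  start_date <- as.Date(start_date)
  if (is.na(start_date)) abort("`start_date` is not a valid date.")

  if (is.null(populations)) {
    populations <- round(seq(600000, 1500000, length.out = n_regions))
  }
  if (length(populations) != n_regions) {
    abort("`populations` must have one entry per region.")
  }
  if (any(populations < 0)) abort("populations must be non-negative.")

  if (is.null(n_dma)) n_dma <- max(1L, ceiling(n_regions / 2))
  n_dma <- as.integer(n_dma)
  if (n_dma < 1 || n_dma > n_regions) abort("`n_dma` must be in [1, n_regions].")

  if (is.null(seasonal_peaks)) {
    amps <- seq(0.8, 1.6, length.out = n_regions)
    seasonal_peaks <- lapply(seq_len(n_regions), function(i) {
      data.frame(
        peak_doy = c(100, 265),
        amplitude = c(amps[i], 0.45 * amps[i]),
        width_days = c(25, 18)
      )
    })
  }
  if (length(seasonal_peaks) != n_regions) {
    abort("`seasonal_peaks` must have one element per region.")
  }
  for (pk in seasonal_peaks) {
    if (!all(c("peak_doy", "amplitude", "width_days") %in% names(pk))) {
      abort("each seasonal_peaks element needs peak_doy, amplitude, width_days.")
    }
    if (any(pk$width_days <= 0)) abort("seasonal peak `width_days` must be > 0.")
    if (any(pk$amplitude < 0)) abort("seasonal peak `amplitude` must be >= 0.")
  }

  if (is.null(relevant_fraction_link)) {
    base <- relevant_fraction_base
    bpost <- coupling_posts
    relevant_fraction_link <- function(a) pmin(1, pmax(0, base * (1 + bpost * a)))
  }
  if (!is.function(relevant_fraction_link)) {
    abort("`relevant_fraction_link` must be a function of the latent level.")
  }

  terms <- as_term_list(terms)
  trend_scale <- rep_len(trend_scale, n_regions)

  structure(
    list(
      n_regions = n_regions, n_days = n_days, start_date = start_date,
      seasonal_peaks = seasonal_peaks, trend_sd = trend_sd,
      coupling_ed = coupling_ed, coupling_posts = coupling_posts,
      coupling_search = coupling_search,
      baseline_ed_rate = baseline_ed_rate,
      baseline_post_rate = baseline_post_rate,
      relevant_fraction_base = relevant_fraction_base,
      relevant_fraction_link = relevant_fraction_link,
      search_base = search_base, search_noise_sd = search_noise_sd,
      anomaly_sd = anomaly_sd, anomaly_ar = anomaly_ar,
      weekly_pattern = weekly_pattern, populations = populations,
      n_dma = n_dma, contamination_rate = contamination_rate,
      nonkeyword_fraction = nonkeyword_fraction, terms = terms,
      stream_trend_sd = stream_trend_sd,
      share_trend_across_regions = share_trend_across_regions,
      trend_scale = trend_scale, seed = as.integer(seed)
    ),
    class = "aw_sim_config"
  )
}

#' Data-sufficiency thresholds for region inclusion
#'
#' Regions are retained for the validation battery only when their population
#' and surveillance volumes support a dense enough daily series: at least
#' `min_population` inhabitants, at least `min_ed_per_100k` allergy-coded ED
#' encounters per 100,000 people, and at least `min_posts_per_100k`
#' allergy-relevant posts per 100,000 people, all totalled over the analysis
#' window. Values exactly at a threshold pass.
#'
#' @param min_ed_per_100k Minimum allergy-coded ED encounters per 100,000.
#' @param min_posts_per_100k Minimum allergy-relevant posts per 100,000.
#' @param min_population Minimum region population.
#' @return A list of class `aw_thresholds`.
#' @export
quality_thresholds <- function(min_ed_per_100k = 450,
                               min_posts_per_100k = 80,
                               min_population = 500000) {
  stopifnot_scalar_number(min_ed_per_100k, "min_ed_per_100k", min = 0)
  stopifnot_scalar_number(min_posts_per_100k, "min_posts_per_100k", min = 0)
  stopifnot_scalar_number(min_population, "min_population", min = 0)
  structure(
    list(
      min_ed_per_100k = min_ed_per_100k,
      min_posts_per_100k = min_posts_per_100k,
      min_population = min_population
    ),
    class = "aw_thresholds"
  )
}

#' Season windows over the calendar year
#'
#' Month-aligned seasonal windows covering the year without overlap. Defaults:
#' spring March-May (the dominant allergy season), summer June-August, fall
#' September-October (the secondary season), winter November-February.
#' Winter spans the year boundary: winter of year Y runs November Y through
#' February Y+1.
#'
#' @param windows Named list mapping season name to the integer months it
#'   covers.
#' @return A list of class `aw_seasons`.
#' @export
season_windows <- function(windows = list(
                             spring = 3:5,
                             summer = 6:8,
                             fall = 9:10,
                             winter = c(11, 12, 1, 2)
                           )) {
  months <- sort(unlist(windows))
  if (!identical(as.integer(months), 1:12)) {
    abort("season windows must cover months 1..12 exactly once.")
  }
  structure(windows, class = "aw_seasons")
}

season_of_month <- function(month, windows = season_windows()) {
  lookup <- character(12)
  for (s in names(windows)) lookup[windows[[s]]] <- s
  lookup[month]
}
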