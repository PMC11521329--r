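#' Run the full statistical validation battery per region
#'
#' For each region, validates the internet streams against the clinical
#' stream the way the surveillance design requires: Canova-Hansen seasonal
#' stability on each stream (on weekly aggregates, period 52 by default);
#' bidirectional two-step Engle-Granger between each internet stream and the
#' ED stream; a Johansen trace test on the (ED, posts, search) triple when a
#' search stream is present; and zero-lag Pearson correlations of the raw
#' series and of both residual variants (seasonal-dummy and STL).
#'
#' Inputs are expected to be 7-day-smoothed ([rolling_mean_7d()]) and
#' quality-filtered upstream; passing a `qc_report` (from
#' [quality_filter()]) enforces the latter — any non-included region present
#' in `series` raises an error. Sporadic interior missing values are
#' linearly interpolated before testing (with a warning); the cointegration
#' machinery needs contiguous series.
#'
#' @param series Long surveillance tibble with an `ed_count` stream and at
#'   least one internet stream (`post_probability`, `allergy_posts`,
#'   `search_probability`).
#' @param qc_report Optional report from [quality_filter()].
#' @param internet_streams Internet streams to pair with the ED stream.
#' @param ch_period Canova-Hansen period on weekly aggregates (default 52).
#' @param johansen_lags,johansen_det Johansen specification (defaults: VAR
#'   lag 7 for weekly dynamics in daily data; constant restricted to the
#'   cointegrating relation).
#' @param stl_period Period for the STL residualization (default 365).
#' @return A tibble with one row per region x internet stream x direction
#'   carrying all statistics, critical values, and flags. Per-region
#'   p-values are reported as-is, with no multiple-testing adjustment across
#'   regions.
#' @export
run_validation_battery <- function(series,
                                   qc_report = NULL,
                                   internet_streams = c("post_probability", "search_probability"),
                                   ch_period = 52,
                                   johansen_lags = 7,
                                   johansen_det = "rconst",
                                   stl_period = 365) {
  check_series(series)
  regions <- unique(series$region_id)
  if (!is.null(qc_report)) {
    bad <- setdiff(regions, qc_report$region_id[qc_report$included])
    if (length(bad)) {
      abort(paste0(
        "region(s) failing the quality filter present in input: ",
        paste(bad, collapse = ", "), "; filter upstream."
      ))
    }
  }
  streams_avail <- unique(series$stream)
  if (!"ed_count" %in% streams_avail) abort("battery needs an `ed_count` stream.")
  internet_streams <- intersect(internet_streams, streams_avail)
  if (!length(internet_streams)) abort("no internet stream found in `series`.")

  get_stream <- function(reg, st) {
    s <- series[series$region_id == reg & series$stream == st, c("date", "value")]
    dplyr::arrange(s, .data$date)
  }
  fill_interior <- function(x) {
    ok <- which(!is.na(x))
    if (!length(ok)) return(x)
    rng <- ok[1]:ok[length(ok)]
    n_int <- sum(is.na(x[rng]))
    if (n_int) {
      warn(sprintf("interpolating %d interior missing value(s) for the battery.", n_int))
      x[rng] <- zoo::na.approx(x[rng])
    }
    x
  }

  rows <- purrr::map(regions, function(reg) {
    ed <- get_stream(reg, "ed_count")
    ed$value <- fill_interior(ed$value)
    ch_of <- function(st) {
      v <- fill_interior(get_stream(reg, st)$value)
      v <- v[!is.na(v)]
      tryCatch(
        suppressWarnings(canova_hansen(weekly_means(v), ch_period))$recommended_order,
        error = function(e) NA_integer_
      )
    }
    ch_ed <- ch_of("ed_count")

    jo_rank <- NA_integer_
    if (all(c("search_probability") %in% streams_avail)) {
      post_stream <- intersect(c("post_probability", "allergy_posts"), streams_avail)[1]
      if (!is.na(post_stream)) {
        triple <- cbind(
          ed = ed$value,
          posts = fill_interior(get_stream(reg, post_stream)$value),
          search = fill_interior(get_stream(reg, "search_probability")$value)
        )
        keep <- complete.cases(triple)
        first <- which(keep)[1]
        last <- max(which(keep))
        jo_rank <- tryCatch(
          johansen_trace(triple[first:last, , drop = FALSE],
                         lag_order = johansen_lags,
                         deterministic = johansen_det)$selected_rank,
          error = function(e) NA_integer_
        )
      }
    }

    purrr::map(internet_streams, function(st) {
      net <- get_stream(reg, st)
      net$value <- fill_interior(net$value)
      keep <- complete.cases(ed$value, net$value)
      ed_v <- ed$value[keep]
      net_v <- net$value[keep]
      dates <- ed$date[keep]

      eg <- engle_granger(ed_v, net_v, check_i1 = FALSE)
      raw <- pearson_zero_lag(ed_v, net_v)
      res_par <- tryCatch({
        rp_ed <- seasonal_dummy_residuals(tibble(date = dates, value = ed_v))$value
        rp_net <- seasonal_dummy_residuals(tibble(date = dates, value = net_v))$value
        pearson_zero_lag(rp_ed, rp_net)
      }, error = function(e) tibble(r = NA_real_, p_value = NA_real_, n = NA_integer_, status = "error"))
      res_stl <- tryCatch({
        rs_ed <- stl_residuals(tibble(date = dates, value = ed_v), period = stl_period)$value
        rs_net <- stl_residuals(tibble(date = dates, value = net_v), period = stl_period)$value
        pearson_zero_lag(rs_ed, rs_net)
      }, error = function(e) tibble(r = NA_real_, p_value = NA_real_, n = NA_integer_, status = "error"))

      dplyr::mutate(
        eg$directions,
        region_id = reg,
        internet_stream = st,
        ch_order_ed = ch_ed,
        ch_order_internet = ch_of(st),
        johansen_rank = jo_rank,
        pearson_raw = raw$r,
        pearson_raw_p = raw$p_value,
        pearson_resid_parametric = res_par$r,
        pearson_resid_parametric_p = res_par$p_value,
        pearson_resid_stl = res_stl$r,
        pearson_resid_stl_p = res_stl$p_value,
        .before = 1
      )
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}
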