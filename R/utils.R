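# Internal helpers shared across modules.

# Deterministic sub-stream seed derivation: FNV-1a over a key string, folded
# with the master seed. Keeps independent generators per (region, stream, ...)
# so adding regions never perturbs existing draws. Result is kept below 2^31.
substream_seed <- function(seed, ...) {
  key <- paste(c(...), collapse = "/")
  h <- 2166136261
  for (b in utf8ToInt(key)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  as.integer((h + as.numeric(seed) * 2654435761) %% 2147483647)
}

stopifnot_scalar_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if ((strict && x <= min) || (!strict && x < min)) {
    abort(sprintf("`%s` must be %s %s.", name, if (strict) ">" else ">=", min))
  }
  invisible(x)
}

# Circular distance between day-of-year values on a 365.25-day wrap, so
# seasonal peaks near Jan 1 behave correctly.
circular_doy_distance <- function(doy, peak, period = 365.25) {
  d <- abs(doy - peak) %% period
  pmin(d, period - d)
}

day_of_year <- function(dates) {
  as.integer(format(dates, "%j"))
}

iso_week <- function(dates) {
  format(dates, "%G-W%V")
}

month_of <- function(dates) {
  as.integer(format(dates, "%m"))
}

year_of <- function(dates) {
  as.integer(format(dates, "%Y"))
}

# Columns every long surveillance series table must carry.
series_cols <- c("region_id", "date", "stream", "value")

check_series <- function(series, arg = "series") {
  if (!is.data.frame(series) || !all(series_cols %in% names(series))) {
    abort(sprintf(
      "`%s` must be a data frame with columns %s.",
      arg, paste(series_cols, collapse = ", ")
    ))
  }
  invisible(series)
}

count_streams <- c("ed_count", "allergy_posts", "total_posts")
probability_streams <- c("post_probability", "search_probability")

is_probability_stream <- function(stream) stream %in% probability_streams
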