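#' Parametric seasonal residuals (seasonal-dummy regression)
#'
#' Least-squares regression of a daily series on an intercept, 11
#' calendar-month indicators, and a linear time index; the residuals are the
#' "parametric" deseasonalized anomalies. Missing values are carried through
#' (residual missing where the input is missing).
#'
#' @param series Long tibble for a single series: columns `date` and `value`
#'   (additional id columns are preserved). At least 2 years of daily data.
#' @return The input tibble with `value` replaced by the residuals.
#' @export
seasonal_dummy_residuals <- function(series) {
  if (!all(c("date", "value") %in% names(series))) {
    abort("`series` must have `date` and `value` columns.")
  }
  if (anyDuplicated(series$date)) {
    abort("`series` must be a single series (duplicate dates found).")
  }
  series <- dplyr::arrange(series, .data$date)
  if (nrow(series) < 730) abort("need at least 2 years of daily data.")
  mo <- factor(month_of(series$date), levels = 1:12)
  present <- !is.na(series$value)
  if (!any(present)) abort("series is all missing.")
  missing_months <- setdiff(levels(mo), unique(as.character(mo[present])))
  if (length(missing_months)) {
    abort(paste0(
      "month(s) with no data: ", paste(missing_months, collapse = ", "),
      "; seasonal dummies cannot be estimated."
    ))
  }
  tindex <- as.numeric(series$date - series$date[1])
  fit <- lm(series$value ~ mo + tindex, na.action = na.exclude)
  dplyr::mutate(series, value = as.numeric(residuals(fit)))
}

#' Nonparametric seasonal residuals (STL remainder)
#'
#' Remainder component of a robust seasonal-trend decomposition by LOESS
#' (STL) at the given period. Interior missing values are filled by linear
#' interpolation before decomposing (a warning reports how many); leading
#' and trailing missing values yield missing residuals.
#'
#' @param series Long tibble for a single series (`date`, `value`).
#' @param period Seasonal period in days (default 365, annual seasonality in
#'   daily data). Must satisfy `period < n/2`.
#' @return The input tibble with `value` replaced by the STL remainder.
#' @export
stl_residuals <- function(series, period = 365) {
  if (!all(c("date", "value") %in% names(series))) {
    abort("`series` must have `date` and `value` columns.")
  }
  if (anyDuplicated(series$date)) {
    abort("`series` must be a single series (duplicate dates found).")
  }
  series <- dplyr::arrange(series, .data$date)
  n <- nrow(series)
  if (period >= n / 2) abort("`period` must be smaller than half the series length.")
  x <- series$value
  ok <- which(!is.na(x))
  if (!length(ok)) abort("series is all missing.")
  core <- x[ok[1]:ok[length(ok)]]
  n_interp <- sum(is.na(core))
  if (n_interp) {
    warn(sprintf("interpolating %d interior missing value(s) before STL.", n_interp))
    core <- zoo::na.approx(core)
  }
  if (length(core) < 2 * period) {
    abort("need at least 2 full periods of data for STL.")
  }
  dec <- stl(ts(core, frequency = period), s.window = "periodic", robust = TRUE)
  rem <- as.numeric(dec$time.series[, "remainder"])
  out <- rep(NA_real_, n)
  out[ok[1]:ok[length(ok)]] <- rem
  out[is.na(x)] <- NA_real_   # interpolated days carry no observed residual
  dplyr::mutate(series, value = out)
}

#' Zero-lag Pearson correlation
#'
#' Sample product-moment correlation of two aligned series with no time
#' shift, with the two-sided p-value from the t transform. Pairs with any
#' missing value are dropped; at least 10 complete pairs are required. If
#' either input has zero variance over the complete pairs the correlation is
#' undefined and reported explicitly as such (`NA`, `status = "undefined"`),
#' never as 0.
#'
#' @param a,b Aligned numeric series.
#' @return One-row tibble: `r`, `p_value`, `n`, `status`.
#' @export
pearson_zero_lag <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) abort("`a` and `b` must be aligned (equal length).")
  ok <- complete.cases(a, b)
  a <- a[ok]
  b <- b[ok]
  n <- length(a)
  if (n < 10) abort("need at least 10 complete pairs.")
  if (sd(a) == 0 || sd(b) == 0) {
    return(tibble(r = NA_real_, p_value = NA_real_, n = n, status = "undefined"))
  }
  ct <- cor.test(a, b, method = "pearson", alternative = "two.sided")
  tibble(
    r = unname(ct$estimate),
    p_value = ct$p.value,
    n = n,
    status = "ok"
  )
}
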