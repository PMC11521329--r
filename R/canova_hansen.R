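#' Canova-Hansen test for seasonal stability
#'
#' Tests the null of a deterministic (stable) seasonal pattern against the
#' alternative of a seasonal unit root at the given period, using the joint
#' LM-type statistic over all seasonal frequencies: residuals from a
#' regression on trigonometric seasonal terms are cumulated, and the
#' statistic is the normalized trace of their outer product weighted by a
#' Bartlett-kernel long-run covariance with the short Newey-West truncation
#' lag `round(4 * (n/100)^0.25)` (a longer truncation absorbs the very
#' nonstationarity under test and destroys power). The 5% critical value
#' uses the
#' `0.269 * period^0.928` approximation to the generalized von Mises
#' distribution, which permits arbitrary periods. The recommended seasonal
#' differencing order is 1 iff the null is rejected at 5%.
#'
#' At least 3 full periods of data are required; fewer than 5 triggers a
#' warning, since the statistic is then poorly calibrated.
#'
#' @param x Numeric series (complete).
#' @param period Seasonal period (>= 2). For daily surveillance series the
#'   battery aggregates to weekly means and uses period 52.
#' @return An object of class `aw_ch`: statistic, period, 5% critical value,
#'   and `recommended_order` (0 or 1).
#' @export
canova_hansen <- function(x, period) {
  if (!is.numeric(period) || length(period) != 1 || period < 2) {
    abort("`period` must be a single number >= 2.")
  }
  period <- as.integer(period)
  x <- as.numeric(x)
  if (anyNA(x)) abort("`x` must be complete for the Canova-Hansen test.")
  n <- length(x)
  n_periods <- n / period
  if (n_periods < 3) abort("need at least 3 full periods of data.")
  if (n_periods < 5) {
    warn("fewer than 5 full periods: Canova-Hansen statistic is poorly calibrated.")
  }
  if (sd(x) == 0) abort("degenerate input: constant series.")

  tt <- seq_len(n)
  m2 <- floor(period / 2)
  fmat <- matrix(0, n, 2 * m2)
  for (i in seq_len(m2)) {
    fmat[, 2 * i - 1] <- cos(2 * pi * i * tt / period)
    fmat[, 2 * i] <- sin(2 * pi * i * tt / period)
  }
  R1 <- fmat[, seq_len(period - 1L), drop = FALSE]
  e <- residuals(lm(x ~ R1))

  fhat_aux <- R1 * e                       # N x (s-1)
  fhat <- apply(fhat_aux, 2, cumsum)
  ltrunc <- max(1L, min(round(4 * (n / 100)^0.25), n - 1L))
  omega <- crossprod(fhat_aux)
  for (kk in seq_len(ltrunc)) {
    w <- 1 - kk / (ltrunc + 1)
    gamma_k <- crossprod(
      fhat_aux[seq_len(n - kk), , drop = FALSE],
      fhat_aux[(kk + 1):n, , drop = FALSE]
    )
    omega <- omega + w * (gamma_k + t(gamma_k))
  }
  omega <- omega / n
  stat <- sum(diag(qr.solve(omega, crossprod(fhat), tol = 1e-25))) / n^2
  cv5 <- 0.269 * period^0.928
  structure(
    list(
      statistic = stat,
      period = period,
      n_periods = n_periods,
      crit_value_5pct = cv5,
      recommended_order = as.integer(stat > cv5)
    ),
    class = "aw_ch"
  )
}

#' @export
print.aw_ch <- function(x, ...) {
  cat(sprintf(
    "Canova-Hansen seasonal stability: stat = %.3f (5%% cv %.3f), period %d, %.1f periods\n",
    x$statistic, x$crit_value_5pct, x$period, x$n_periods
  ))
  cat("  recommended seasonal differencing order:", x$recommended_order, "\n")
  invisible(x)
}

#' @rdname canova_hansen
#' @param x An `aw_ch` object.
#' @param ... Unused.
#' @export
tidy.aw_ch <- function(x, ...) {
  tibble(
    statistic = x$statistic,
    period = x$period,
    n_periods = x$n_periods,
    crit_value_5pct = x$crit_value_5pct,
    recommended_order = x$recommended_order
  )
}

# Aggregate a daily series to non-overlapping weekly means (full weeks only),
# the battery's preprocessing before Canova-Hansen at period 52.
weekly_means <- function(x) {
  n_full <- length(x) %/% 7L
  if (n_full < 1) abort("series shorter than one week.")
  colMeans(matrix(x[seq_len(n_full * 7L)], nrow = 7L))
}
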