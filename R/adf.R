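# MacKinnon (2010) response-surface critical values: cv = b_inf + b1/T + b2/T^2.
# Rows 1%/5%/10%. "coint2_constant" is the two-variable cointegration case
# with a constant in the cointegrating regression (Engle-Granger step 2).
mackinnon_params <- list(
  none = rbind(
    `1%` = c(-2.56574, -2.2358, -3.627),
    `5%` = c(-1.94100, -0.2686, -3.365),
    `10%` = c(-1.61682, 0.2656, -2.714)
  ),
  constant = rbind(
    `1%` = c(-3.43035, -6.5393, -16.786),
    `5%` = c(-2.86154, -2.8903, -4.234),
    `10%` = c(-2.56677, -1.5384, -2.809)
  ),
  trend = rbind(
    `1%` = c(-3.95877, -9.0531, -28.428),
    `5%` = c(-3.41049, -4.3904, -9.036),
    `10%` = c(-3.12705, -2.5856, -3.925)
  ),
  coint2_constant = rbind(
    `1%` = c(-3.89644, -10.9519, -22.527),
    `5%` = c(-3.33613, -6.1101, -6.823),
    `10%` = c(-3.04445, -4.2412, -2.720)
  )
)

mackinnon_cv <- function(kind, nobs) {
  p <- mackinnon_params[[kind]]
  setNames(p[, 1] + p[, 2] / nobs + p[, 3] / nobs^2, rownames(p))
}

# OLS by QR with coefficient t-statistics; errors on rank deficiency.
ols_fit <- function(X, y) {
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) abort("collinear regressors in unit-root regression.")
  beta <- qr.coef(qr_, y)
  res <- as.numeric(y - X %*% beta)
  neff <- length(y)
  k <- ncol(X)
  rss <- sum(res^2)
  s2 <- rss / (neff - k)
  Rinv <- backsolve(qr.R(qr_), diag(k))
  se <- sqrt(s2 * rowSums(Rinv^2))
  list(beta = beta, se = se, rss = rss, resid = res, neff = neff, k = k)
}

# Dickey-Fuller regression at a given lag order; returns the t-statistic on
# the lagged level. start_t fixes the estimation sample (for common-sample
# lag comparison); NULL uses all observations the lag order allows.
df_regression <- function(x, k, deterministic, start_t = NULL) {
  n <- length(x)
  dx <- diff(x)
  first <- if (is.null(start_t)) k + 2L else start_t
  tt <- seq.int(first, n)
  y <- dx[tt - 1L]
  X <- cbind(ylag = x[tt - 1L])
  if (k > 0) {
    for (j in seq_len(k)) X <- cbind(X, dx[tt - 1L - j])
  }
  if (deterministic == "constant") X <- cbind(X, const = 1)
  if (deterministic == "trend") X <- cbind(X, const = 1, trend = tt)
  fit <- ols_fit(X, y)
  list(
    stat = fit$beta[1] / fit$se[1],
    aic = fit$neff * log(fit$rss / fit$neff) + 2 * fit$k,
    neff = fit$neff
  )
}

#' Augmented Dickey-Fuller unit-root test
#'
#' Left-tailed test of the null of a unit root via the lagged-difference
#' regression. With `max_lags = "auto"` the lag order is chosen by AIC over
#' 0..p_max with Schwert's rule p_max = floor(12 (n/100)^(1/4)), compared on
#' a common estimation sample and then refit on the longest sample the chosen
#' lag allows. Critical values come from the MacKinnon (2010)
#' response-surface tabulation for the chosen deterministic term.
#'
#' @param x Numeric series. Missing values are allowed only at the edges.
#' @param deterministic `"constant"` (default), `"none"`, or `"trend"`
#'   (constant plus linear trend).
#' @param max_lags `"auto"` or a fixed non-negative lag count.
#' @return An object of class `aw_adf`: statistic, lags, nobs, critical
#'   values at 1/5/10%, and reject flags per level.
#' @export
adf_test <- function(x, deterministic = c("constant", "none", "trend"),
                     max_lags = "auto") {
  deterministic <- match.arg(deterministic)
  adf_core(x, deterministic, max_lags, cv_kind = switch(deterministic,
    none = "none", constant = "constant", trend = "trend"
  ))
}

adf_core <- function(x, deterministic, max_lags, cv_kind) {
  x <- as.numeric(x)
  ok <- which(!is.na(x))
  if (!length(ok)) abort("series is all missing.")
  x <- x[ok[1]:ok[length(ok)]]
  if (anyNA(x)) abort("interior missing values are not allowed in adf_test().")
  n <- length(x)
  if (n < 34) abort("series too short for the unit-root regression (need >= 34 usable observations).")
  if (sd(x) == 0) abort("degenerate input: constant series has no unit-root test.")

  pmax <- if (identical(max_lags, "auto")) {
    floor(12 * (n / 100)^0.25)
  } else {
    as.integer(max_lags)
  }
  if (pmax < 0) abort("`max_lags` must be >= 0.")
  pmax <- min(pmax, n - 32L)

  if (identical(max_lags, "auto") && pmax > 0) {
    start_t <- pmax + 2L
    aics <- vapply(
      0:pmax,
      function(k) df_regression(x, k, deterministic, start_t = start_t)$aic,
      numeric(1)
    )
    k <- (0:pmax)[which.min(aics)]
  } else {
    k <- pmax
  }
  fit <- df_regression(x, k, deterministic)
  cvals <- mackinnon_cv(cv_kind, fit$neff)
  structure(
    list(
      statistic = unname(fit$stat),
      lags = k,
      nobs = fit$neff,
      deterministic = deterministic,
      critical_values = cvals,
      reject = setNames(fit$stat < cvals, names(cvals))
    ),
    class = "aw_adf"
  )
}

#' @export
print.aw_adf <- function(x, ...) {
  cat("Augmented Dickey-Fuller test (", x$deterministic, ")\n", sep = "")
  cat(sprintf(
    "  statistic = %.4f, lags = %d, n = %d\n", x$statistic, x$lags, x$nobs
  ))
  cat("  critical values:",
      paste(sprintf("%s %.3f", names(x$critical_values), x$critical_values),
            collapse = ", "), "\n")
  invisible(x)
}

#' @rdname adf_test
#' @param x An `aw_adf` object.
#' @param ... Unused.
#' @export
tidy.aw_adf <- function(x, ...) {
  tibble(
    statistic = x$statistic,
    lags = x$lags,
    nobs = x$nobs,
    deterministic = x$deterministic,
    cv_1pct = x$critical_values[["1%"]],
    cv_5pct = x$critical_values[["5%"]],
    cv_10pct = x$critical_values[["10%"]],
    reject_1pct = x$reject[["1%"]],
    reject_5pct = x$reject[["5%"]],
    reject_10pct = x$reject[["10%"]]
  )
}
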