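# Osterwald-Lenum (1992) asymptotic trace critical values, indexed by the
# number of common trends k - r (rows) at 10/5/1%. "rconst": constant
# restricted to the cointegrating relation; "const": unrestricted constant.
johansen_cv_tables <- list(
  rconst = rbind(
    c(7.52, 9.24, 12.97),
    c(17.85, 19.96, 24.60),
    c(32.00, 34.91, 41.07),
    c(49.65, 53.12, 60.16),
    c(71.86, 76.07, 84.45)
  ),
  const = rbind(
    c(2.69, 3.76, 6.65),
    c(13.33, 15.41, 20.04),
    c(26.79, 29.68, 35.65),
    c(43.95, 47.21, 54.46),
    c(64.84, 68.52, 76.07)
  )
)

#' Johansen trace test for cointegration rank
#'
#' Likelihood-based determination of the number of cointegrating relations
#' among 2-5 jointly I(1) series, via reduced-rank regression of the VECM.
#' The trace statistic for hypothesized rank r is
#' \eqn{-T \sum_{i>r} \log(1-\lambda_i)}; the selected rank is the smallest
#' r whose trace statistic does not exceed the 5% critical value
#' (Osterwald-Lenum 1992). One common stochastic trend among k series
#' implies rank k-1.
#'
#' @param y Matrix or data frame of aligned, complete series (columns).
#' @param lag_order VAR lag order p (the VECM uses p-1 lagged differences).
#'   Default 7 captures weekly dynamics in daily data.
#' @param deterministic `"rconst"` (constant restricted to the cointegrating
#'   relation, the default) or `"const"` (unrestricted constant).
#' @return An object of class `aw_johansen`: eigenvalues, a tibble of trace
#'   statistics with critical values per hypothesized rank, and
#'   `selected_rank`.
#' @export
johansen_trace <- function(y, lag_order = 7, deterministic = c("rconst", "const")) {
  deterministic <- match.arg(deterministic)
  y <- as.matrix(y)
  storage.mode(y) <- "double"
  k <- ncol(y)
  if (k < 2 || k > 5) abort("johansen_trace() handles 2 to 5 series.")
  if (anyNA(y)) abort("series must be complete (no missing values).")
  p <- as.integer(lag_order)
  if (p < 1) abort("`lag_order` must be >= 1.")
  n <- nrow(y)
  if (n < 20 * (p + 1)) {
    abort("too few observations: need n >= 20 * (lag_order + 1).")
  }
  if (qr(sweep(y, 2, colMeans(y)))$rank < k) {
    abort("collinear input series.")
  }

  dy <- diff(y)
  tt <- seq.int(p + 1, n)         # equation dates in level indexing
  z0 <- dy[tt - 1L, , drop = FALSE]
  z1 <- y[tt - 1L, , drop = FALSE]
  if (deterministic == "rconst") z1 <- cbind(z1, const = 1)
  z2 <- NULL
  if (p > 1) {
    z2 <- do.call(cbind, lapply(seq_len(p - 1L), function(j) dy[tt - 1L - j, , drop = FALSE]))
  }
  if (deterministic == "const") z2 <- cbind(z2, const = 1)
  teff <- length(tt)

  partial_out <- function(z, w) {
    if (is.null(w)) return(z)
    z - w %*% qr.coef(qr(w), z)
  }
  r0 <- partial_out(z0, z2)
  r1 <- partial_out(z1, z2)
  s00 <- crossprod(r0) / teff
  s11 <- crossprod(r1) / teff
  s01 <- crossprod(r0, r1) / teff
  m <- solve(s11, t(s01)) %*% solve(s00, s01)
  lambda <- sort(Re(eigen(m, only.values = TRUE)$values), decreasing = TRUE)[seq_len(k)]
  lambda <- pmin(pmax(lambda, 0), 1 - 1e-12)

  trace_stats <- vapply(
    0:(k - 1L),
    function(r) -teff * sum(log(1 - lambda[(r + 1):k])),
    numeric(1)
  )
  cvt <- johansen_cv_tables[[deterministic]]
  cvs <- cvt[k - (0:(k - 1L)), , drop = FALSE]
  tab <- tibble(
    rank_null = 0:(k - 1L),
    trace = trace_stats,
    cv_10pct = cvs[, 1],
    cv_5pct = cvs[, 2],
    cv_1pct = cvs[, 3],
    reject_5pct = trace_stats > cvs[, 2]
  )
  selected <- if (all(tab$reject_5pct)) k else min(tab$rank_null[!tab$reject_5pct])
  structure(
    list(
      eigenvalues = lambda,
      table = tab,
      selected_rank = as.integer(selected),
      k = k,
      lag_order = p,
      deterministic = deterministic,
      n = teff
    ),
    class = "aw_johansen"
  )
}

#' @export
print.aw_johansen <- function(x, ...) {
  cat(sprintf(
    "Johansen trace test: k = %d, lag order = %d, deterministic = %s, T = %d\n",
    x$k, x$lag_order, x$deterministic, x$n
  ))
  print(as.data.frame(x$table), row.names = FALSE)
  cat("  selected rank (5%):", x$selected_rank, "\n")
  invisible(x)
}

#' @rdname johansen_trace
#' @param x An `aw_johansen` object.
#' @param ... Unused.
#' @export
tidy.aw_johansen <- function(x, ...) {
  dplyr::mutate(x$table, selected_rank = x$selected_rank)
}
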