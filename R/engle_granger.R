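#' Bidirectional two-step Engle-Granger cointegration test
#'
#' Step 1 regresses one series on the other (with intercept) by least
#' squares; step 2 runs an augmented Dickey-Fuller regression on the step-1
#' residuals with no deterministic term, judged against two-variable
#' cointegration critical values (MacKinnon 2010, constant-in-regression
#' case). Because the choice of dependent variable is arbitrary, the test is
#' run in both directions (`y_on_x` and `x_on_y`); cointegration in both
#' directions is the stronger statement. If an ADF test on either level
#' series rejects a unit root at 5%, a warning is attached: Engle-Granger
#' presumes both inputs are I(1).
#'
#' @param y,x Aligned numeric series (missing values only at shared edges);
#'   at least 50 complete observations.
#' @param max_lags Lag policy for the residual ADF regression (see
#'   [adf_test()]).
#' @param check_i1 Run level ADF tests and attach a warning flag if either
#'   input looks stationary in levels (default `TRUE`).
#' @return An object of class `aw_eg` whose `directions` element is a tibble
#'   with one row per direction: slope, intercept, residual unit-root
#'   statistic, critical values, and cointegration flags at 1/5/10%.
#' @export
engle_granger <- function(y, x, max_lags = "auto", check_i1 = TRUE) {
  y <- as.numeric(y)
  x <- as.numeric(x)
  if (length(y) != length(x)) abort("`y` and `x` must be aligned (equal length).")
  ok <- complete.cases(y, x)
  y <- y[ok]
  x <- x[ok]
  n <- length(y)
  if (n < 50) abort("Engle-Granger requires at least 50 complete observations.")
  if (sd(x) == 0 || sd(y) == 0) abort("zero-variance input series.")

  one_direction <- function(dep, reg, label) {
    X <- cbind(intercept = 1, slope = reg)
    fit <- ols_fit(X, dep)
    resid <- fit$resid
    if (sd(resid) < 1e-10 * sd(dep)) {
      abort("degenerate input: step-1 residuals are (numerically) zero; the series are identical up to an affine map.")
    }
    ur <- adf_core(resid, deterministic = "none", max_lags = max_lags,
                   cv_kind = "coint2_constant")
    tibble(
      direction = label,
      intercept = unname(fit$beta[1]),
      slope = unname(fit$beta[2]),
      statistic = ur$statistic,
      lags = ur$lags,
      nobs = ur$nobs,
      cv_1pct = ur$critical_values[["1%"]],
      cv_5pct = ur$critical_values[["5%"]],
      cv_10pct = ur$critical_values[["10%"]],
      cointegrated_1pct = ur$reject[["1%"]],
      cointegrated_5pct = ur$reject[["5%"]],
      cointegrated_10pct = ur$reject[["10%"]]
    )
  }

  directions <- dplyr::bind_rows(
    one_direction(y, x, "y_on_x"),
    one_direction(x, y, "x_on_y")
  )
  levels_warning <- FALSE
  if (check_i1) {
    rej <- vapply(list(y, x), function(s) {
      tryCatch(adf_test(s, "constant")$reject[["5%"]], error = function(e) FALSE)
    }, logical(1))
    if (any(rej)) {
      levels_warning <- TRUE
      warn("a level series rejects a unit root at 5%; Engle-Granger presumes both inputs are I(1).")
    }
  }
  structure(
    list(directions = directions, n = n, levels_warning = levels_warning),
    class = "aw_eg"
  )
}

#' @export
print.aw_eg <- function(x, ...) {
  cat("Engle-Granger two-step cointegration test (both directions), n =", x$n, "\n")
  print(as.data.frame(x$directions[, c(
    "direction", "slope", "statistic", "cv_1pct",
    "cointegrated_1pct", "cointegrated_5pct"
  )]), row.names = FALSE)
  if (x$levels_warning) cat("  note: a level series looked stationary (I(1) premise in doubt)\n")
  invisible(x)
}

#' @rdname engle_granger
#' @param ... Unused.
#' @export
tidy.aw_eg <- function(x, ...) x$directions

#' @rdname engle_granger
#' @export
glance.aw_eg <- function(x, ...) {
  tibble(
    n = x$n,
    cointegrated_1pct_both = all(x$directions$cointegrated_1pct),
    cointegrated_5pct_both = all(x$directions$cointegrated_5pct),
    levels_warning = x$levels_warning
  )
}
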