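make_regions <- function(n = 1, pops = 1e5) {
  cfg <- sim_config(n_regions = n, populations = rep_len(pops, n))
  generate_regions(cfg)
}

test_that("daily aggregation bins by UTC calendar day with explicit zeros", {
  reg <- make_regions(1)
  ev <- tibble::tibble(
    region_id = "r01",
    timestamp = as.POSIXct(c(
      "2020-01-02 10:00:00", "2020-01-02 23:59:00", "2020-01-03 00:01:00"
    ), tz = "UTC")
  )
  s <- aggregate_daily(ev, reg, date_range = as.Date(c("2020-01-01", "2020-01-05")))
  expect_equal(s$value, c(0, 2, 1, 0, 0))
  expect_equal(sum(s$value), nrow(ev))
  expect_equal(discard_log(s)$n_discarded, 0L)

  # events outside the range are logged and excluded, not silently dropped
  s2 <- aggregate_daily(ev, reg, date_range = as.Date(c("2020-01-03", "2020-01-05")))
  expect_equal(sum(s2$value), 1)
  expect_equal(discard_log(s2)$n_discarded, 2L)
})

test_that("post probability is allergy/total with 0/0 missing", {
  d <- as.Date("2020-01-01") + 0:3
  series <- dplyr::bind_rows(
    tibble::tibble(region_id = "r", date = d, stream = "allergy_posts", value = c(5, 0, 7, 0)),
    tibble::tibble(region_id = "r", date = d, stream = "total_posts", value = c(50, 50, 7, 0))
  )
  p <- post_probability(series)
  expect_equal(p$value, c(0.1, 0, 1, NA))
  bad <- series
  bad$value[1] <- 100
  expect_error(post_probability(bad), "exceeds")
})

test_that("7-day centered smoothing removes day-of-week patterns exactly", {
  d <- as.Date("2020-01-06") + 0:69   # starts a Monday
  pattern <- c(1, 4, 2, 8, 5, 7, 3)
  s <- tibble::tibble(
    region_id = "r", date = d, stream = "ed_count",
    value = rep(pattern, 10)
  )
  sm <- rolling_mean_7d(s)
  interior <- sm$value[4:67]
  expect_equal(interior, rep(mean(pattern), length(interior)))

  ramp <- tibble::tibble(region_id = "r", date = d[1:7], stream = "ed_count", value = 1:7)
  expect_equal(rolling_mean_7d(ramp)$value[4], 4)

  const <- tibble::tibble(region_id = "r", date = d, stream = "ed_count", value = 2)
  expect_true(all(rolling_mean_7d(const)$value == 2))
})

test_that("smoothing requires at least 4 of 7 window values", {
  d <- as.Date("2020-01-01") + 0:13
  v <- c(1, 2, 3, NA, NA, NA, NA, 8, 9, 10, 11, 12, 13, 14)
  s <- tibble::tibble(region_id = "r", date = d, stream = "ed_count", value = v)
  sm <- rolling_mean_7d(s)
  # day 5 window (days 2..8) has 3 non-missing -> missing
  expect_true(is.na(sm$value[5]))
  # day 8 window (days 5..11) has 4 non-missing -> mean of those
  expect_equal(sm$value[8], mean(c(8, 9, 10, 11)))
  # edge day 1 window (days 1..4) has 3 non-missing -> missing
  expect_true(is.na(sm$value[1]))
})

test_that("smoothing shrinks white-noise variance by about 1/7", {
  ratios <- withr::with_seed(17, replicate(60, {
    d <- as.Date("2020-01-01") + 0:999
    x <- rnorm(1000)
    sm <- rolling_mean_7d(tibble::tibble(
      region_id = "r", date = d, stream = "ed_count", value = x
    ))$value
    var(sm[4:997]) / var(x)
  }))
  expect_equal(mean(ratios), 1 / 7, tolerance = 0.2)
})

test_that("per-capita scaling is linear and correct", {
  reg <- make_regions(1, pops = 1e6)
  d <- as.Date("2020-01-01")
  s <- tibble::tibble(region_id = "r01", date = d, stream = "ed_count", value = 45)
  expect_equal(per_capita(s, reg)$value, 4.5)
  reg2 <- make_regions(1, pops = 1e5)
  expect_equal(per_capita(s, reg2)$value, 45)
  a <- dplyr::mutate(s, value = 10)
  b <- dplyr::mutate(s, value = 35)
  expect_equal(
    per_capita(dplyr::mutate(s, value = a$value + b$value), reg)$value,
    per_capita(a, reg)$value + per_capita(b, reg)$value
  )
  reg_bad <- make_regions(1)
  reg_bad$population <- 0
  expect_error(per_capita(s, reg_bad), "positive")
})

test_that("date-range exclusion masks values but keeps the index", {
  d <- seq(as.Date("2019-01-01"), as.Date("2021-12-31"), by = "day")
  s <- tibble::tibble(region_id = "r", date = d, stream = "ed_count", value = 1)
  masked <- exclude_date_range(s, list(c("2020-01-01", "2020-12-31")))
  expect_equal(nrow(masked), nrow(s))
  expect_equal(sum(is.na(masked$value)), 366)  # 2020 is a leap year
  expect_true(all(is.na(masked$value[format(masked$date, "%Y") == "2020"])))
  expect_identical(exclude_date_range(s, list()), s)
  all_gone <- exclude_date_range(s, list(range(d)))
  expect_equal(nrow(all_gone), nrow(s))
  expect_true(all(is.na(all_gone$value)))
  expect_error(exclude_date_range(s, list(c("2020-12-31", "2020-01-01"))), "malformed")
})

test_that("quality filter applies the population and volume thresholds inclusively", {
  mk_series <- function(ed_total, post_total, pop) {
    reg <- make_regions(1, pops = pop)
    d <- as.Date("2020-01-01") + 0:9
    list(
      series = dplyr::bind_rows(
        tibble::tibble(region_id = "r01", date = d, stream = "ed_count",
                       value = c(ed_total, rep(0, 9))),
        tibble::tibble(region_id = "r01", date = d, stream = "allergy_posts",
                       value = c(post_total, rep(0, 9)))
      ),
      regions = reg
    )
  }
  # paper-style inclusion case
  x <- mk_series(ed_total = 500 * 6, post_total = 100 * 6, pop = 6e5)
  expect_true(quality_filter(x$series, x$regions)$included)
  # failing the ED criterion alone excludes
  x <- mk_series(ed_total = 400 * 6, post_total = 100 * 6, pop = 6e5)
  r <- quality_filter(x$series, x$regions)
  expect_false(r$included)
  expect_false(r$pass_ed)
  expect_true(r$pass_posts && r$pass_population)
  # exact boundary values are included ("fewer than" excludes)
  x <- mk_series(ed_total = 450 * 5, post_total = 80 * 5, pop = 5e5)
  expect_true(quality_filter(x$series, x$regions)$included)
})

test_that("quality filter is monotone in its thresholds", {
  cfg <- sim_config(n_regions = 6, n_days = 400, seed = 31,
                    populations = seq(3e5, 1.3e6, length.out = 6))
  reg <- generate_regions(cfg)
  st <- generate_streams(generate_latent(cfg), cfg)
  base <- quality_filter(st, reg)
  for (th in list(
    quality_thresholds(min_ed_per_100k = 2000),
    quality_thresholds(min_posts_per_100k = 1e5),
    quality_thresholds(min_population = 1e6)
  )) {
    harder <- quality_filter(st, reg, th)
    expect_true(all(harder$included <= base$included))
  }
})

test_that("replicate averaging handles missing values per day", {
  d <- as.Date("2020-01-01")
  reps <- dplyr::bind_rows(
    tibble::tibble(region_id = "r", date = d, stream = "search_probability",
                   value = 0.2, replicate = 1L),
    tibble::tibble(region_id = "r", date = d, stream = "search_probability",
                   value = 0.4, replicate = 2L),
    tibble::tibble(region_id = "r", date = d + 1, stream = "search_probability",
                   value = NA_real_, replicate = 1L),
    tibble::tibble(region_id = "r", date = d + 1, stream = "search_probability",
                   value = 0.6, replicate = 2L)
  )
  avg <- average_replicates(reps)
  expect_equal(avg$value, c(0.3, 0.6))
  expect_error(average_replicates(list()), "no replicates")
})
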