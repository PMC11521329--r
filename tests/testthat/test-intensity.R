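prob_series <- function(values_by_region, start = "2019-01-01") {
  n <- length(values_by_region[[1]])
  dplyr::bind_rows(purrr::imap(values_by_region, function(v, rid) {
    tibble::tibble(
      region_id = rid,
      date = as.Date(start) + 0:(n - 1),
      stream = "post_probability",
      value = v
    )
  }))
}

test_that("annual Z-scores standardize region means exactly", {
  s <- prob_series(list(
    a = rep(0.01, 365), b = rep(0.02, 365), c = rep(0.03, 365)
  ))
  z <- annual_intensity_z(s)
  expect_equal(z$annual_z[order(z$region_id)], c(-1, 0, 1))
  expect_equal(mean(z$annual_z), 0, tolerance = 1e-9)
  expect_equal(sd(z$annual_z), 1, tolerance = 1e-9)
  # location invariance
  s2 <- dplyr::mutate(s, value = value + 0.5)
  expect_equal(annual_intensity_z(s2)$annual_z, z$annual_z)
  # scale invariance
  s3 <- dplyr::mutate(s, value = value * 7)
  expect_equal(annual_intensity_z(s3)$annual_z, z$annual_z)
  expect_error(annual_intensity_z(s[s$region_id == "a", ]), "2 regions")
  expect_error(
    annual_intensity_z(prob_series(list(a = rep(0.1, 365), b = rep(0.1, 365)))),
    "zero cross-region variance"
  )
})

test_that("seasonal Z-scores isolate a region-specific fall bump", {
  n <- 730
  doy <- rep(1:365, length.out = n)
  fall_bump <- 0.05 * exp(-(doy - 274)^2 / (2 * 15^2))
  s <- prob_series(list(
    a = 0.02 + fall_bump,
    b = rep(0.02, n),
    c = rep(0.021, n),
    d = rep(0.019, n)
  ))
  z <- seasonal_intensity_z(s)
  fall <- z[z$season == "fall", ]
  expect_equal(fall$region_id[which.max(fall$seasonal_z)], "a")
  for (season in unique(z$season)) {
    zz <- z$seasonal_z[z$season == season]
    expect_equal(mean(zz), 0, tolerance = 1e-9)
    expect_equal(sd(zz), 1, tolerance = 1e-9)
  }
})

test_that("a uniform region has seasonal means equal to its annual mean", {
  s <- prob_series(list(a = rep(0.033, 730), b = rep(0.05, 730)))
  z <- seasonal_intensity_z(s)
  expect_true(all(abs(z$mean_value[z$region_id == "a"] - 0.033) < 1e-12))
})

test_that("peak detection finds the seasonal maximum with earliest-tie rule", {
  n <- 365
  doy <- 1:365
  bump <- 0.1 * exp(-(doy - 100)^2 / (2 * 12^2))
  s <- prob_series(list(a = bump, b = rep(0.02, n)))
  pk <- peak_date(s, season = "spring")
  expect_equal(pk$peak_doy[pk$region_id == "a"], 100)
  # flat series: earliest day of the window
  expect_equal(
    pk$peak_date[pk$region_id == "b"],
    as.Date("2019-03-01")
  )
  # all-missing window reported as undefined
  s_na <- prob_series(list(a = replace(bump, 60:151, NA), b = rep(0.02, n)))
  pk_na <- peak_date(s_na, season = "spring")
  expect_equal(pk_na$status[pk_na$region_id == "a"], "undefined")
  expect_true(is.na(pk_na$peak_doy[pk_na$region_id == "a"]))
})

test_that("winter peak windows span the year boundary", {
  n <- 500
  s <- prob_series(list(a = rep(0.01, n), b = rep(0.02, n)), start = "2019-01-01")
  # spike in January 2020 must belong to winter of season-year 2019
  s$value[s$region_id == "a" & s$date == as.Date("2020-01-15")] <- 0.5
  pk <- peak_date(s, season = "winter")
  row <- pk[pk$region_id == "a" & pk$season_year == 2019, ]
  expect_equal(row$peak_date, as.Date("2020-01-15"))
})

test_that("weekly matrix has one row per region ordered north to south", {
  cfg <- sim_config(n_regions = 4, n_days = 140, seed = 9)
  reg <- generate_regions(cfg)
  st <- generate_streams(generate_latent(cfg), cfg)
  p <- post_probability(st)
  wm <- weekly_matrix(p, reg)
  m <- attr(wm, "matrix")
  expect_equal(nrow(m), 4)
  expect_equal(ncol(m), length(unique(format(p$date, "%G-W%V"))))
  expect_equal(rownames(m), reg$region_id[order(-reg$lat)])
  # constant series gives a constant row
  cst <- prob_series(list(a = rep(0.1, 70), b = rep(0.2, 70)))
  m2 <- attr(weekly_matrix(cst), "matrix")
  expect_true(all(abs(m2["a", ] - 0.1) < 1e-12))
})

test_that("map_intensity assembles all components and plots", {
  cfg <- sim_config(n_regions = 3, n_days = 740, seed = 19)
  reg <- generate_regions(cfg)
  st <- generate_streams(generate_latent(cfg), cfg)
  obs <- dplyr::bind_rows(st, post_probability(st))
  res <- map_intensity(obs, reg)
  expect_s3_class(res, "aw_intensity")
  expect_equal(nrow(res$annual), 3)
  expect_setequal(unique(res$seasonal$season), c("spring", "summer", "fall", "winter"))
  expect_true(all(c("spring", "fall") %in% res$peaks$season))
  p1 <- autoplot(res)
  expect_s3_class(p1, "ggplot")
  p2 <- plot_intensity_map(res$annual, reg)
  expect_s3_class(p2, "ggplot")
})
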