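test_that("generate_regions tiles rectangles into DMA groups deterministically", {
  cfg <- sim_config(n_regions = 4, n_dma = 2, seed = 1)
  reg <- generate_regions(cfg)
  expect_equal(nrow(reg), 4)
  expect_equal(as.integer(table(reg$dma_id)), c(2L, 2L))
  expect_equal(reg$dma_id, c("dma01", "dma01", "dma02", "dma02"))
  # axis-aligned rectangles: 5-vertex closed rings, no overlap of interiors
  for (g in reg$geometry) expect_equal(nrow(g), 5)
  centroids <- cbind(reg$lon, reg$lat)
  owner <- assign_point_to_region(centroids[, 1], centroids[, 2], reg)
  expect_equal(owner, reg$region_id)

  reg2 <- generate_regions(cfg)
  expect_identical(reg, reg2)

  one <- generate_regions(sim_config(n_regions = 1))
  expect_equal(nrow(one), 1)
  expect_equal(unique(one$dma_id), "dma01")

  expect_error(
    generate_regions(sim_config(n_regions = 2, populations = c(0, 1000))),
    "population"
  )
})

test_that("latent process is an exact deterministic annual function without noise", {
  cfg <- sim_config(
    n_regions = 1, n_days = 800, trend_sd = 0, anomaly_sd = 0,
    seasonal_peaks = list(data.frame(peak_doy = 100, amplitude = 1, width_days = 10)),
    seed = 7
  )
  lat <- generate_latent(cfg)
  expect_equal(lat$value, lat$seasonal)
  expect_equal(day_max <- as.integer(format(lat$date[which.max(lat$value)], "%j")), 100L)
  # exact annual repetition across years for the same day of year
  doy <- as.integer(format(lat$date, "%j"))
  expect_equal(lat$value[doy == 50][1], lat$value[doy == 50][2], tolerance = 1e-3)
})

test_that("latent widths must be positive", {
  expect_error(
    sim_config(seasonal_peaks = rep(list(
      data.frame(peak_doy = 100, amplitude = 1, width_days = 0)
    ), 8)),
    "width_days"
  )
})

test_that("random-walk trend has i.i.d. normal increments with the configured sd", {
  cfg <- sim_config(n_regions = 1, n_days = 10000, trend_sd = 0.3, anomaly_sd = 0, seed = 11)
  lat <- generate_latent(cfg)
  d <- diff(lat$trend)
  expect_equal(var(d), 0.3^2, tolerance = 0.05)
  expect_gt(shapiro.test(sample(d, 3000))$p.value, 1e-4)
})

test_that("identical parameters and seed give identical seasonal and shared trend", {
  cfg <- sim_config(
    n_regions = 2, n_days = 500, share_trend_across_regions = TRUE, seed = 3,
    seasonal_peaks = rep(list(data.frame(peak_doy = 120, amplitude = 1, width_days = 20)), 2),
    populations = c(7e5, 7e5)
  )
  lat <- generate_latent(cfg)
  r1 <- lat[lat$region_id == "r01", ]
  r2 <- lat[lat$region_id == "r02", ]
  expect_identical(r1$seasonal, r2$seasonal)
  expect_identical(r1$trend, r2$trend)
})

test_that("streams honour population scaling and conserve counts", {
  cfg <- tiny_config(populations = c(0, 8e5))
  lat <- generate_latent(cfg)
  st <- generate_streams(lat, cfg)
  zero <- st[st$region_id == "r01" & st$stream %in% c("ed_count", "total_posts", "allergy_posts"), ]
  expect_true(all(zero$value == 0))
  # allergy posts can never exceed total posts
  wide <- tidyr::pivot_wider(st[st$stream %in% c("allergy_posts", "total_posts"), ],
    names_from = "stream", values_from = "value"
  )
  expect_true(all(wide$allergy_posts <= wide$total_posts))
  # search probability bounded
  sp <- st$value[st$stream == "search_probability"]
  expect_true(all(sp >= 0 & sp <= 1))
  # determinism
  expect_identical(st, generate_streams(lat, cfg))
  # NaN latent rejected
  lat_bad <- lat
  lat_bad$value[5] <- NaN
  expect_error(generate_streams(lat_bad, cfg), "NaN")
})

test_that("uncoupled streams are uncorrelated after seasonal adjustment", {
  # with all couplings zero the streams share only the weekly pattern;
  # weekly-smoothed series should show no systematic association
  rs <- withr::with_seed(99, replicate(40, {
    seed <- sample.int(1e6, 1)
    cfg <- sim_config(
      n_regions = 1, n_days = 400, seed = seed,
      coupling_ed = 0, coupling_posts = 0, coupling_search = 0
    )
    st <- generate_streams(generate_latent(cfg), cfg)
    sm <- rolling_mean_7d(st)
    w <- tidyr::pivot_wider(sm, names_from = "stream", values_from = "value")
    cor(w$ed_count, w$allergy_posts, use = "complete.obs")
  }))
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("generated posts contain keywords, hit the contamination rate, and replay exactly", {
  cfg <- sim_config(n_regions = 2, n_days = 400, seed = 5, contamination_rate = 0.2)
  lat <- generate_latent(cfg)
  posts <- generate_posts(lat, cfg)
  expect_gt(nrow(posts), 10000)
  rel <- posts[posts$label == "relevant", ]
  expect_true(all(keyword_match(rel$text, cfg$terms)))
  # contamination among keyword-matching posts
  km <- posts[keyword_match(posts$text, cfg$terms), ]
  frac_irr <- mean(km$label == "irrelevant")
  expect_equal(frac_irr, 0.2, tolerance = 0.02 / 0.2)
  expect_identical(posts, generate_posts(lat, cfg))
  expect_error(sim_config(terms = term_list(character(), character())), "at least one")
})

test_that("daily aggregation of generated posts reproduces the allergy stream exactly", {
  cfg <- sim_config(n_regions = 2, n_days = 200, seed = 13)
  lat <- generate_latent(cfg)
  st <- generate_streams(lat, cfg)
  posts <- generate_posts(lat, cfg)
  reg <- generate_regions(cfg)
  rel <- posts[posts$label == "relevant", ]
  rel$assigned_region <- rel$region_id
  agg <- aggregate_daily(rel, reg,
    stream = "allergy_posts",
    date_range = c(cfg$start_date, cfg$start_date + cfg$n_days - 1)
  )
  target <- dplyr::arrange(
    st[st$stream == "allergy_posts", ], region_id, date
  )
  agg <- dplyr::arrange(agg, region_id, date)
  expect_equal(agg$value, target$value)
})

test_that("series replicates are unbiased, clipped, and reproducible", {
  cfg <- tiny_config()
  st <- generate_streams(generate_latent(cfg), cfg)
  sp <- st[st$stream == "search_probability" & st$region_id == "r01", ]
  expect_identical(
    resample_series_replicates(sp, 3, noise_sd = 0, seed = 1)$value,
    rep(sp$value, 3)
  )
  reps <- resample_series_replicates(sp, 100, noise_sd = 0.05, seed = 2)
  expect_true(all(reps$value >= 0 & reps$value <= 1))
  avg <- average_replicates(reps)
  # CLT: pointwise mean of 100 replicates within 3*sd/10 of the input
  # (clipping makes this conservative away from the boundaries)
  interior <- sp$value > 0.15 & sp$value < 0.85
  expect_true(all(abs(avg$value[interior] - sp$value[interior]) < 3 * 0.05 / 10))
  expect_identical(
    resample_series_replicates(sp, 1, noise_sd = 0.1, seed = 3),
    resample_series_replicates(sp, 1, noise_sd = 0.1, seed = 3)
  )
  expect_error(resample_series_replicates(sp, 2, noise_sd = -1), "noise_sd")
})
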