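# Reproduction experiments: each function re-runs one of the package's
# calibration/validation studies from scratch under a seed and returns the
# summary quantities. They are what scripts/acceptance.R and the acceptance
# tests execute.

#' Monte-Carlo validation experiments
#'
#' Each `experiment_*()` function regenerates its study inputs from scratch
#' under `seed`, runs the package's machinery, and returns a one-row tibble
#' of summary quantities. They document — and make reproducible — the
#' statistical properties the package claims: test size and power,
#' cointegration-rank recovery, seasonal-stability behaviour, residual
#' diagnostics, end-to-end battery behaviour on the synthetic generator,
#' agreement with small exact oracles, the data-sufficiency rules, and
#' classifier performance.
#'
#' @param n_reps Number of Monte-Carlo replicates.
#' @param seed Integer seed; every replicate derives its own sub-seed.
#' @param n Series length (days).
#' @name experiments
NULL

# Two independent I(1) daily series with deterministic annual seasonality:
# the null for Engle-Granger. Scales follow the generator's latent units
# (seasonal amplitude ~1, random-walk innovation sd 0.1).
eg_null_pair <- function(n = 1460) {
  doy <- (seq_len(n) - 1) %% 365
  x <- cumsum(rnorm(n, 0, 0.1)) + exp(-(doy - 100)^2 / (2 * 25^2))
  y <- cumsum(rnorm(n, 0, 0.1)) + 0.8 * exp(-(doy - 150)^2 / (2 * 30^2))
  list(x = x, y = y)
}

#' @rdname experiments
#' @export
experiment_eg_size <- function(n_reps = 500, seed = 1, n = 1460) {
  rej <- withr::with_seed(substream_seed(seed, "eg_size"), {
    vapply(seq_len(n_reps), function(i) {
      p <- eg_null_pair(n)
      engle_granger(p$y, p$x, check_i1 = FALSE)$directions$cointegrated_5pct[1]
    }, logical(1))
  })
  tibble(rejection_rate_5pct = mean(rej), n_reps = n_reps, n = n)
}

#' @rdname experiments
#' @export
experiment_eg_power <- function(n_reps = 100, seed = 1, n = 1460) {
  res <- withr::with_seed(substream_seed(seed, "eg_power"), {
    vapply(seq_len(n_reps), function(i) {
      x <- cumsum(rnorm(n))
      # stationary AR(1) noise with sd 10% of the trend innovation sd
      y <- 2 * x + as.numeric(arima.sim(list(ar = 0.7), n, sd = 0.1))
      eg <- engle_granger(y, x, check_i1 = FALSE)
      c(
        both = all(eg$directions$cointegrated_1pct),
        slope = eg$directions$slope[1]
      )
    }, numeric(2))
  })
  tibble(
    power_1pct = mean(res["both", ]),
    slope_median = median(res["slope", ]),
    n_reps = n_reps, n = n
  )
}

#' @rdname experiments
#' @export
experiment_johansen_rank <- function(n_reps = 50, seed = 1, n = 1460) {
  ranks <- withr::with_seed(substream_seed(seed, "johansen"), {
    vapply(seq_len(n_reps), function(i) {
      w <- cumsum(rnorm(n))
      shared <- cbind(w + rnorm(n), 0.6 * w + rnorm(n), 1.4 * w + rnorm(n))
      indep <- cbind(cumsum(rnorm(n)), cumsum(rnorm(n)), cumsum(rnorm(n)))
      c(
        shared = johansen_trace(shared, lag_order = 7)$selected_rank,
        indep = johansen_trace(indep, lag_order = 7)$selected_rank
      )
    }, numeric(2))
  })
  tibble(
    rank2_rate_shared_trend = mean(ranks["shared", ] == 2),
    rank0_rate_independent = mean(ranks["indep", ] == 0),
    n_reps = n_reps, n = n
  )
}

#' @rdname experiments
#' @export
experiment_canova_hansen <- function(n_reps = 100, seed = 1) {
  res <- withr::with_seed(substream_seed(seed, "ch"), {
    vapply(seq_len(n_reps), function(i) {
      stable <- rep(sin(2 * pi * (1:12) / 12) + 0.4 * cos(4 * pi * (1:12) / 12), 20) +
        rnorm(240, 0, 0.5)
      walk_by_season <- apply(matrix(rnorm(240, 0, 0.5), nrow = 12), 1, cumsum)
      srw <- as.vector(t(walk_by_season)) + rnorm(240, 0, 0.5)
      c(
        stable = canova_hansen(stable, 12)$recommended_order,
        srw = canova_hansen(srw, 12)$recommended_order
      )
    }, numeric(2))
  })
  tibble(
    stable_order0_rate = mean(res["stable", ] == 0),
    seasonal_walk_order1_rate = mean(res["srw", ] == 1),
    n_reps = n_reps, n = 240
  )
}

#' @rdname experiments
#' @export
experiment_residualization <- function(seed = 1, n = 1460) {
  d <- as.Date("2016-01-01") + seq_len(n) - 1
  month_step <- tibble(date = d, value = as.numeric(format(d, "%m"))^2)
  dummy_max <- max(abs(seasonal_dummy_residuals(month_step)$value))
  stl_stats <- withr::with_seed(substream_seed(seed, "stl"), {
    tt <- seq_len(n)
    x <- sin(2 * pi * tt / 365) + 0.001 * tt + rnorm(n, 0, 0.05)
    r <- stl_residuals(tibble(date = d, value = x), period = 365)$value
    c(sd = sd(r), adf_reject = adf_test(r, "constant")$reject[["5%"]])
  })
  tibble(
    dummy_residual_max = dummy_max,
    stl_residual_sd = stl_stats[["sd"]],
    stl_residual_adf_reject_5pct = stl_stats[["adf_reject"]],
    n = n
  )
}

# One region-level battery run on generator streams.
battery_once <- function(cfg) {
  st <- generate_streams(generate_latent(cfg), cfg)
  obs <- dplyr::bind_rows(st, post_probability(st))
  sm <- rolling_mean_7d(obs[obs$stream %in%
    c("ed_count", "post_probability", "search_probability"), ])
  suppressWarnings(run_validation_battery(sm))
}

#' @rdname experiments
#' @export
experiment_battery_coupled <- function(n_reps = 50, seed = 1, n = 1460) {
  pass <- vapply(seq_len(n_reps), function(i) {
    cfg <- sim_config(
      n_regions = 1, n_days = n,
      seed = substream_seed(seed, "battery_coupled", i)
    )
    rep <- battery_once(cfg)
    pp <- rep[rep$internet_stream == "post_probability", ]
    all(pp$cointegrated_1pct) &&
      all(pp$pearson_resid_parametric > 0.5) &&
      all(pp$pearson_resid_stl > 0.5)
  }, logical(1))
  tibble(coupled_pass_rate = mean(pass), n_reps = n_reps, n = n)
}

#' @rdname experiments
#' @export
experiment_battery_null <- function(n_reps = 50, seed = 1, n = 1460) {
  pass <- vapply(seq_len(n_reps), function(i) {
    cfg <- sim_config(
      n_regions = 1, n_days = n,
      coupling_ed = 0, coupling_posts = 0, coupling_search = 0,
      stream_trend_sd = 0.06,
      seed = substream_seed(seed, "battery_null", i)
    )
    rep <- battery_once(cfg)
    pp <- rep[rep$internet_stream == "post_probability", ]
    !all(pp$cointegrated_1pct)
  }, logical(1))
  tibble(null_not_cointegrated_rate = mean(pass), n_reps = n_reps, n = n)
}

#' @rdname experiments
#' @export
experiment_exact_oracles <- function(seed = 1) {
  # Pearson vs the direct product-moment formula on 1,000 random vectors
  pearson_dev <- withr::with_seed(substream_seed(seed, "pearson"), {
    max(vapply(seq_len(1000), function(i) {
      n <- sample(10:80, 1)
      a <- rnorm(n)
      b <- rnorm(n)
      am <- a - mean(a); bm <- b - mean(b)
      direct <- sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
      abs(pearson_zero_lag(a, b)$r - direct)
    }, numeric(1)))
  })
  # 7-day smoothing of a pure day-of-week pattern is exactly flat inside
  d <- as.Date("2020-01-06") + 0:139
  pattern <- c(2, 9, 4, 7, 1, 8, 5)
  sm <- rolling_mean_7d(tibble(
    region_id = "r", date = d, stream = "ed_count",
    value = rep(pattern, 20)
  ))$value
  weekly_dev <- max(abs(sm[4:137] - mean(pattern)))
  # even-odd assignment vs winding-number oracle on 1,000 points
  poly <- cbind(
    lon = c(0, 4, 4, 2.5, 2, 1, 0, 0),
    lat = c(0, 0, 2, 1.2, 3, 1.5, 2, 0)
  )
  regions <- tibble(
    region_id = "p", name = "P", population = 1e5, dma_id = "d",
    lon = 2, lat = 1, geometry = list(poly)
  )
  wn_inside <- function(px, py, ring) {
    ring <- ring[-nrow(ring), , drop = FALSE]
    n <- nrow(ring)
    wn <- 0
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      il <- (ring[j, 1] - ring[i, 1]) * (py - ring[i, 2]) -
        (px - ring[i, 1]) * (ring[j, 2] - ring[i, 2])
      if (ring[i, 2] <= py) {
        if (ring[j, 2] > py && il > 0) wn <- wn + 1
      } else if (ring[j, 2] <= py && il < 0) wn <- wn - 1
    }
    wn != 0
  }
  pip_agree <- withr::with_seed(substream_seed(seed, "pip"), {
    pts <- cbind(runif(1000, -0.5, 4.5), runif(1000, -0.5, 3.5))
    got <- !is.na(assign_point_to_region(pts[, 1], pts[, 2], regions))
    oracle <- vapply(seq_len(1000), function(i) wn_inside(pts[i, 1], pts[i, 2], poly), logical(1))
    mean(got == oracle)
  })
  # Z-score standardization is exact
  z_dev <- withr::with_seed(substream_seed(seed, "z"), {
    s <- dplyr::bind_rows(lapply(1:12, function(i) tibble(
      region_id = sprintf("r%02d", i), date = as.Date("2019-01-01") + 0:364,
      stream = "post_probability", value = runif(365, 0, 0.2)
    )))
    z <- annual_intensity_z(s)$annual_z
    max(abs(mean(z)), abs(sd(z) - 1))
  })
  tibble(
    pearson_oracle_max_abs_diff = pearson_dev,
    weekly_pattern_removal_max_dev = weekly_dev,
    point_in_region_oracle_agreement = pip_agree,
    zscore_standardization_max_dev = z_dev
  )
}

#' @rdname experiments
#' @export
experiment_amplitude_recovery <- function(n_reps = 50, seed = 1, n_regions = 20) {
  amps <- seq(0.8, 1.6, length.out = n_regions)
  rho <- vapply(seq_len(n_reps), function(i) {
    cfg <- sim_config(
      n_regions = n_regions, n_days = 1460,
      trend_sd = 0, anomaly_sd = 0.15,
      seasonal_peaks = lapply(amps, function(a) {
        data.frame(peak_doy = 100, amplitude = a, width_days = 25)
      }),
      seed = substream_seed(seed, "amp", i)
    )
    st <- generate_streams(generate_latent(cfg), cfg)
    z <- seasonal_intensity_z(post_probability(st))
    spring <- z[z$season == "spring", ]
    cor(
      spring$seasonal_z[match(sprintf("r%02d", seq_len(n_regions)), spring$region_id)],
      amps,
      method = "spearman"
    )
  }, numeric(1))
  tibble(
    spearman_median = median(rho),
    spearman_min = min(rho),
    n_reps = n_reps, n_regions = n_regions
  )
}

#' @rdname experiments
#' @export
experiment_peak_recovery <- function(n_reps = 50, seed = 1) {
  truth <- c(r01 = 90, r02 = 120)
  hits <- vapply(seq_len(n_reps), function(i) {
    cfg <- sim_config(
      n_regions = 2, n_days = 1460,
      trend_sd = 0, anomaly_sd = 0.05,
      populations = c(1.5e6, 1.5e6),
      seasonal_peaks = list(
        data.frame(peak_doy = 90, amplitude = 2, width_days = 12),
        data.frame(peak_doy = 120, amplitude = 2, width_days = 12)
      ),
      seed = substream_seed(seed, "peak", i)
    )
    st <- generate_streams(generate_latent(cfg), cfg)
    p <- rolling_mean_7d(post_probability(st))
    pk <- peak_date(p, season = "spring")
    est <- tapply(pk$peak_doy, pk$region_id, median)
    all(abs(est - truth[names(est)]) <= 3)
  }, logical(1))
  tibble(peak_within_3d_rate = mean(hits), n_reps = n_reps)
}

#' @rdname experiments
#' @export
experiment_quality_rules <- function() {
  mk <- function(ed_total, post_total, pop) {
    cfg <- sim_config(n_regions = 1, populations = pop)
    d <- as.Date("2020-01-01") + 0:9
    series <- dplyr::bind_rows(
      tibble(region_id = "r01", date = d, stream = "ed_count",
             value = c(ed_total, rep(0, 9))),
      tibble(region_id = "r01", date = d, stream = "allergy_posts",
             value = c(post_total, rep(0, 9)))
    )
    quality_filter(series, generate_regions(cfg))$included
  }
  cases <- c(
    low_ed_excluded = !mk(400 * 6, 100 * 6, 6e5),
    low_posts_excluded = !mk(500 * 6, 79 * 6, 6e5),
    low_population_excluded = !mk(500 * 4.99999, 100 * 4.99999, 499999),
    boundary_included = mk(450 * 5, 80 * 5, 5e5)
  )
  tibble(rules_correct_rate = mean(cases), n_cases = length(cases))
}

#' @rdname experiments
#' @export
experiment_classifier <- function(seed = 1) {
  sep <- withr::with_seed(substream_seed(seed, "sep_corpus"), {
    rel_words <- c("pollen", "sneezing", "congested", "antihistamine", "itchy")
    irr_words <- c("bakery", "traffic", "football", "concert", "recipe")
    mk <- function(words, n) {
      vapply(seq_len(n), function(i) {
        paste(sample(words, 3, replace = TRUE), collapse = " ")
      }, character(1))
    }
    tibble(
      text = c(mk(rel_words, 500), mk(irr_words, 500)),
      label = rep(c("relevant", "irrelevant"), each = 500)
    )
  })
  tr <- c(1:250, 501:750)
  cl <- train_classifier(sep[tr, ], seed = substream_seed(seed, "cl1"))
  m_sep <- evaluate_classifier(classify(cl, sep$text[-tr]), sep$label[-tr])

  cfg <- sim_config(
    n_regions = 2, n_days = 300, contamination_rate = 0.2,
    seed = substream_seed(seed, "corpus")
  )
  posts <- generate_posts(generate_latent(cfg), cfg)
  posts <- posts[keyword_match(posts$text, cfg$terms), ]
  idx <- withr::with_seed(substream_seed(seed, "split"), sample(nrow(posts), 4000))
  cl2 <- train_classifier(posts[idx[1:2000], ], seed = substream_seed(seed, "cl2"))
  test <- posts[idx[2001:4000], ]
  m_con <- evaluate_classifier(classify(cl2, test$text), test$label)
  baseline <- mean(test$label == "relevant")
  tibble(
    separable_accuracy = m_sep$accuracy,
    contaminated_accuracy = m_con$accuracy,
    majority_baseline = baseline,
    n_train = 2000, n_test = 2000
  )
}
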