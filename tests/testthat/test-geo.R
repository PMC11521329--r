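test_that("bbox centroids are arithmetic midpoints", {
  expect_equal(bbox_centroid(0, 0, 2, 2), tibble::tibble(lon = 1, lat = 1))
  expect_equal(bbox_centroid(1, 1, 1, 1), tibble::tibble(lon = 1, lat = 1))
  expect_equal(bbox_centroid(-120, 34, -118, 36), tibble::tibble(lon = -119, lat = 35))
  expect_error(bbox_centroid(NaN, 0, 1, 1), "NaN")
  expect_error(bbox_centroid(2, 0, 1, 1), "invalid bounding box")
})

test_that("point assignment follows the even-odd rule and matches a winding-number oracle", {
  square <- function(x0, y0) {
    cbind(lon = c(x0, x0 + 1, x0 + 1, x0, x0), lat = c(y0, y0, y0 + 1, y0 + 1, y0))
  }
  regions <- tibble::tibble(
    region_id = c("a", "b"),
    name = c("A", "B"),
    population = c(1e5, 1e5),
    dma_id = c("d1", "d1"),
    lon = c(0.5, 1.5), lat = c(0.5, 0.5),
    geometry = list(square(0, 0), square(1, 0))
  )
  expect_equal(assign_point_to_region(0.5, 0.5, regions), "a")
  expect_equal(assign_point_to_region(2.5, 0.5, regions), NA_character_)
  # edge between the two squares: lexicographically smallest id wins
  expect_equal(assign_point_to_region(1, 0.5, regions), "a")

  # an irregular simple polygon, checked against an independent
  # winding-number implementation on 1,000 random points
  poly <- cbind(
    lon = c(0, 4, 4, 2.5, 2, 1, 0, 0),
    lat = c(0, 0, 2, 1.2, 3, 1.5, 2, 0)
  )
  one <- tibble::tibble(
    region_id = "p", name = "P", population = 1e5, dma_id = "d",
    lon = 2, lat = 1, geometry = list(poly)
  )
  pts <- withr::with_seed(1, cbind(runif(1000, -0.5, 4.5), runif(1000, -0.5, 3.5)))
  got <- assign_point_to_region(pts[, 1], pts[, 2], one)
  oracle <- vapply(
    seq_len(nrow(pts)),
    function(i) winding_number_inside(pts[i, 1], pts[i, 2], poly),
    logical(1)
  )
  expect_equal(!is.na(got), oracle)
})

test_that("assignment is invariant to ring rotation and vertex order", {
  ring <- cbind(lon = c(0, 2, 2, 0, 0), lat = c(0, 0, 2, 2, 0))
  base <- tibble::tibble(
    region_id = "r", name = "R", population = 1, dma_id = "d",
    lon = 1, lat = 1, geometry = list(ring)
  )
  open_ring <- ring[-5, ]
  rotated <- open_ring[c(3, 4, 1, 2), ]
  reversed <- open_ring[4:1, ]
  pts <- withr::with_seed(2, cbind(runif(200, -1, 3), runif(200, -1, 3)))
  ref <- assign_point_to_region(pts[, 1], pts[, 2], base)
  for (g in list(rotated, reversed)) {
    alt <- base
    alt$geometry <- list(g)
    expect_equal(assign_point_to_region(pts[, 1], pts[, 2], alt), ref)
  }
})

test_that("overlapping regions trigger an ambiguity error", {
  ring <- cbind(lon = c(0, 2, 2, 0, 0), lat = c(0, 0, 2, 2, 0))
  regions <- tibble::tibble(
    region_id = c("a", "b"), name = c("A", "B"),
    population = c(1, 1), dma_id = c("d", "d"),
    lon = 1, lat = 1, geometry = list(ring, ring)
  )
  expect_error(assign_point_to_region(1, 1, regions), "ambiguous")
})

test_that("DMA aggregation sums counts and population-weights probabilities", {
  cfg <- sim_config(n_regions = 2, n_dma = 1, populations = c(1e5, 3e5))
  reg <- generate_regions(cfg)
  d <- as.Date("2020-01-01")
  series <- tibble::tibble(
    region_id = rep(c("r01", "r02"), each = 2),
    date = rep(c(d, d + 1), 2),
    stream = "ed_count",
    value = c(3, 5, 4, 6)
  )
  agg <- aggregate_regions_to_dma(series, reg)
  expect_equal(agg$value, c(7, 11))
  probs <- tibble::tibble(
    region_id = c("r01", "r02"),
    date = d, stream = "post_probability",
    value = c(0.1, 0.4)
  )
  expect_equal(aggregate_regions_to_dma(probs, reg)$value, 0.325)
  # single-region DMA is the identity
  cfg1 <- sim_config(n_regions = 1)
  agg1 <- aggregate_regions_to_dma(
    tibble::tibble(region_id = "r01", date = d, stream = "ed_count", value = 9),
    generate_regions(cfg1)
  )
  expect_equal(agg1$value, 9)
  # unknown stream types cannot be aggregated
  expect_error(
    aggregate_regions_to_dma(
      dplyr::mutate(series, stream = "mystery"), reg
    ),
    "unknown type"
  )
})

test_that("DMA aggregation conserves daily count totals exactly", {
  cfg <- sim_config(n_regions = 5, n_dma = 2, n_days = 60)
  reg <- generate_regions(cfg)
  st <- generate_streams(generate_latent(cfg), cfg)
  counts <- st[st$stream %in% c("ed_count", "allergy_posts", "total_posts"), ]
  agg <- aggregate_regions_to_dma(counts, reg)
  by_day_in <- dplyr::summarise(
    dplyr::group_by(counts, date, stream), v = sum(value), .groups = "drop"
  )
  by_day_out <- dplyr::summarise(
    dplyr::group_by(agg, date, stream), v = sum(value), .groups = "drop"
  )
  expect_equal(dplyr::arrange(by_day_out, stream, date), dplyr::arrange(by_day_in, stream, date))
})
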