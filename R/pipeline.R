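#' Run the end-to-end surveillance pipeline
#'
#' Executes the full analysis on synthetic data: simulate regions, latent
#' process, streams and posts; train and evaluate the relevance classifier
#' on a stratified split of the labeled posts; filter posts (keywords then
#' classifier); assign posts to regions and aggregate to region-day counts;
#' derive the post-probability stream; apply exclusion windows; run the
#' data-sufficiency filter; run the validation battery on the smoothed
#' included regions; and map intensity. All artifacts are written to
#' `out_dir` as plain text, together with a manifest (configuration, seed,
#' version, per-stage record counts) and a structured stage log. Re-running
#' with the same configuration and seed reproduces the outputs
#' byte-identically.
#'
#' @param config An [sim_config()].
#' @param out_dir Output directory (created if absent).
#' @param thresholds An [quality_thresholds()].
#' @param windows An [season_windows()].
#' @param exclude_ranges List of closed date ranges to mask (e.g. a pandemic
#'   year), or `NULL`.
#' @param label_sample Size of the random subset of posts treated as the
#'   manually annotated set (default 4,000, the scale at which manual
#'   labeling is feasible); the classifier is trained and evaluated on a
#'   stratified split of this subset and then applied to all posts.
#' @param train_fraction Fraction of the labeled subset used to train the
#'   classifier (stratified by label; the rest evaluate it).
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the main in-memory results: `regions`,
#'   `classifier_metrics`, `qc`, `report`, `intensity`, `manifest`.
#' @export
run_pipeline <- function(config = sim_config(),
                         out_dir,
                         thresholds = quality_thresholds(),
                         windows = season_windows(),
                         exclude_ranges = NULL,
                         label_sample = 4000,
                         train_fraction = 0.7,
                         verbose = FALSE) {
  stopifnot(inherits(config, "aw_sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, n_in, n_out, note = "") {
    log[[length(log) + 1]] <<- list(stage = name, n_in = n_in, n_out = n_out, note = note)
  }

  say("simulate: %d regions x %d days", config$n_regions, config$n_days)
  regions <- generate_regions(config)
  latent <- generate_latent(config)
  streams <- generate_streams(latent, config)
  posts <- generate_posts(latent, config)
  write_regions_geojson(regions, file.path(out_dir, "regions.geojson"))
  write_posts_jsonl(posts, file.path(out_dir, "posts.jsonl"))
  stage("simulate", 0, nrow(posts))

  say("classifier: %d labeled posts, stratified %d%% train split",
      min(label_sample, nrow(posts)), round(train_fraction * 100))
  labeled_idx <- withr::with_seed(
    substream_seed(config$seed, "labelset"),
    sample(nrow(posts), min(label_sample, nrow(posts)))
  )
  labeled <- posts[labeled_idx, ]
  split <- withr::with_seed(substream_seed(config$seed, "split"), {
    idx <- unlist(lapply(split(seq_len(nrow(labeled)), labeled$label), function(ii) {
      sample(ii, size = floor(length(ii) * train_fraction))
    }))
    sort(idx)
  })
  classifier <- train_classifier(labeled[split, ], seed = substream_seed(config$seed, "classifier"))
  heldout <- labeled[-split, ]
  metrics <- evaluate_classifier(classify(classifier, heldout$text), heldout$label)
  stage("train_classifier", length(split), nrow(heldout),
        sprintf("heldout accuracy %.3f", metrics$accuracy))

  say("filter-posts")
  kept <- filter_posts(posts, config$terms, classifier)
  stage("filter_posts", nrow(posts), nrow(kept))

  say("aggregate")
  kept <- assign_posts_to_regions(kept, regions)
  date_range <- c(config$start_date, config$start_date + config$n_days - 1L)
  allergy_series <- aggregate_daily(kept, regions, stream = "allergy_posts",
                                    date_range = date_range)
  stage("aggregate_daily", nrow(kept), sum(allergy_series$value))
  observed <- dplyr::bind_rows(
    streams[streams$stream %in% c("ed_count", "total_posts", "search_probability"), ],
    allergy_series
  )
  observed <- dplyr::bind_rows(observed, post_probability(observed))
  if (!is.null(exclude_ranges)) {
    observed <- exclude_date_range(observed, exclude_ranges)
  }
  write_series_csv(observed, file.path(out_dir, "series.csv"))

  say("qc")
  qc <- quality_filter(observed, regions, thresholds)
  readr::write_csv(qc, file.path(out_dir, "qc.csv"))
  stage("quality_filter", nrow(regions), sum(qc$included))

  say("validate: %d included regions", sum(qc$included))
  included <- qc$region_id[qc$included]
  battery_input <- observed |>
    dplyr::filter(
      .data$region_id %in% included,
      .data$stream %in% c("ed_count", "post_probability", "search_probability")
    ) |>
    rolling_mean_7d()
  report <- suppressWarnings(
    run_validation_battery(battery_input, qc_report = qc)
  )
  readr::write_csv(report, file.path(out_dir, "report.csv"))
  stage("validation_battery", length(included), nrow(report))

  say("map-intensity")
  prob_series <- observed[observed$region_id %in% included, ]
  intensity <- map_intensity(prob_series, regions, windows)
  readr::write_csv(
    dplyr::left_join(
      intensity$annual,
      tidyr::pivot_wider(intensity$seasonal[, c("region_id", "season", "seasonal_z")],
                         names_from = "season", values_from = "seasonal_z",
                         names_glue = "{season}_z"),
      by = "region_id"
    ),
    file.path(out_dir, "intensity.csv")
  )
  readr::write_csv(intensity$peaks, file.path(out_dir, "peaks.csv"))
  readr::write_csv(attr(intensity$weekly, "long"), file.path(out_dir, "weekly_matrix.csv"))
  stage("map_intensity", length(included), nrow(intensity$annual))

  manifest <- list(
    package_version = as.character(utils::packageVersion("allergywatch")),
    seed = config$seed,
    n_regions = config$n_regions,
    n_days = config$n_days,
    start_date = format(config$start_date),
    thresholds = unclass(thresholds),
    train_fraction = train_fraction,
    exclude_ranges = if (is.null(exclude_ranges)) list() else
      lapply(exclude_ranges, function(r) format(as.Date(r))),
    config_hash = config_hash(config),
    stages = log
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(log, file.path(out_dir, "log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(
    regions = regions, classifier_metrics = metrics, qc = qc,
    report = report, intensity = intensity, manifest = manifest
  ))
}

# Stable hash of the configuration for the run manifest.
config_hash <- function(config) {
  flat <- config
  flat$relevant_fraction_link <- deparse(body(config$relevant_fraction_link))
  flat$terms <- unclass(config$terms)
  flat$start_date <- format(config$start_date)
  if (requireNamespace("digest", quietly = TRUE)) {
    digest::digest(flat, algo = "sha256")
  } else {
    # fall back to a short FNV-style fingerprint of the serialized config
    as.character(substream_seed(0L, paste(deparse(flat), collapse = "")))
  }
}
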