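Package: allergywatch
Title: Internet-Based Surveillance of Seasonal Allergy Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for validating and mapping internet-derived seasonal
    allergy signals against clinical surveillance streams. Provides a
    synthetic-data generator for coupled region-day surveillance streams
    driven by a latent aeroallergen process, keyword filtering and a
    pluggable text-relevance classifier for social posts, geographic
    assignment of geotagged posts to regions, daily aggregation with
    denoising and data-sufficiency rules, a cointegration validation
    battery (augmented Dickey-Fuller, Canova-Hansen seasonal stability,
    bidirectional two-step Engle-Granger, Johansen trace) with dual
    seasonal residualization and zero-lag correlation, and regional
    allergy-intensity mapping as cross-region Z-scores with
    peak-timing detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    zoo
Suggests:
    digest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
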