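# Independent oracles used by the tests. These deliberately do not share
# code with the package implementations they check.

# Product-moment correlation from the definition.
pearson_direct <- function(a, b) {
  am <- a - mean(a)
  bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

# Winding-number point-in-polygon (nonzero rule). On simple polygons it
# agrees with the even-odd rule used by the package.
winding_number_inside <- function(px, py, ring) {
  if (ring[1, 1] == ring[nrow(ring), 1] && ring[1, 2] == ring[nrow(ring), 2]) {
    ring <- ring[-nrow(ring), , drop = FALSE]
  }
  n <- nrow(ring)
  wn <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x1 <- ring[i, 1]; y1 <- ring[i, 2]
    x2 <- ring[j, 1]; y2 <- ring[j, 2]
    is_left <- (x2 - x1) * (py - y1) - (px - x1) * (y2 - y1)
    if (y1 <= py) {
      if (y2 > py && is_left > 0) wn <- wn + 1
    } else {
      if (y2 <= py && is_left < 0) wn <- wn - 1
    }
  }
  wn != 0
}

# Tiny synthetic corpus with disjoint vocabularies per class.
separable_corpus <- function(n_per_class, seed = 1) {
  withr::with_seed(seed, {
    rel_words <- c("pollen", "sneezing", "congested", "antihistamine", "itchy")
    irr_words <- c("bakery", "traffic", "football", "concert", "recipe")
    mk <- function(words, n) {
      vapply(seq_len(n), function(i) {
        paste(sample(words, 3, replace = TRUE), collapse = " ")
      }, character(1))
    }
    tibble::tibble(
      text = c(mk(rel_words, n_per_class), mk(irr_words, n_per_class)),
      label = rep(c("relevant", "irrelevant"), each = n_per_class)
    )
  })
}

# Small default simulation config used across tests (short but long enough
# for the annual machinery).
tiny_config <- function(...) {
  sim_config(n_regions = 2, n_days = 740, seed = 42, ...)
}
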