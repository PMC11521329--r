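#' Term and hashtag list for the keyword pre-filter
#'
#' The keyword stage retains posts containing any term (matched
#' case-insensitively on word boundaries; multi-word phrases allowed) or any
#' hashtag (matched exactly against `#`-tokens). The shipped default covers
#' obvious allergy vocabulary; the list is configuration, not algorithm.
#'
#' @param terms Character vector of lowercase terms/phrases.
#' @param hashtags Character vector of lowercase hashtags starting with `#`.
#' @return A list of class `aw_terms`.
#' @export
term_list <- function(terms, hashtags = character()) {
  terms <- unique(stringr::str_to_lower(trimws(terms)))
  hashtags <- unique(stringr::str_to_lower(trimws(hashtags)))
  if (length(terms) + length(hashtags) == 0 || all(!nzchar(c(terms, hashtags)))) {
    abort("term list must contain at least one term or hashtag.")
  }
  if (any(!nzchar(terms))) abort("empty term supplied.")
  if (length(hashtags) && any(!startsWith(hashtags, "#"))) {
    abort("hashtags must start with '#'.")
  }
  structure(list(terms = terms, hashtags = hashtags), class = "aw_terms")
}

#' @rdname term_list
#' @export
default_terms <- function() {
  term_list(
    terms = c(
      "allergies", "allergy", "allergic", "pollen", "hay fever",
      "antihistamine", "sneezing", "sneeze", "itchy eyes"
    ),
    hashtags = c("#allergies", "#pollen", "#hayfever")
  )
}

as_term_list <- function(x) {
  if (inherits(x, "aw_terms")) return(x)
  if (is.character(x)) return(term_list(x))
  if (is.list(x)) return(term_list(x$terms %||% character(), x$hashtags %||% character()))
  abort("cannot interpret `terms` as a term list.")
}

#' Keyword pre-filter
#'
#' Returns `TRUE` for texts containing at least one term on a word boundary
#' (case-insensitive) or at least one hashtag matching a `#`-token exactly.
#' Empty or missing text never matches.
#'
#' @param text Character vector of post texts.
#' @param terms An [term_list()] object (or character vector of terms).
#' @return Logical vector, one element per text.
#' @export
keyword_match <- function(text, terms) {
  terms <- as_term_list(terms)
  if (!is.character(text)) abort("`text` must be a character vector.")
  out <- rep(FALSE, length(text))
  ok <- !is.na(text) & nzchar(text)
  if (!any(ok)) return(out)
  txt <- text[ok]
  hit <- rep(FALSE, length(txt))
  for (term in terms$terms) {
    pat <- paste0("(?<![\\p{L}\\p{N}])", stringr::str_escape(term), "(?![\\p{L}\\p{N}])")
    hit <- hit | stringr::str_detect(txt, stringr::regex(pat, ignore_case = TRUE))
  }
  if (length(terms$hashtags)) {
    tags <- stringr::str_extract_all(stringr::str_to_lower(txt), "#[\\p{L}\\p{N}_]+")
    hit <- hit | vapply(tags, function(tk) any(tk %in% terms$hashtags), logical(1))
  }
  out[ok] <- hit
  out
}

# Unicode word tokens, case-folded, '#' kept as a token prefix; no stemming.
tokenize_text <- function(text) {
  stringr::str_extract_all(
    stringr::str_to_lower(text),
    "#?[\\p{L}\\p{N}][\\p{L}\\p{N}']*"
  )
}

build_dtm <- function(tokens, vocab) {
  ii <- rep.int(seq_along(tokens), lengths(tokens))
  jj <- match(unlist(tokens, use.names = FALSE), vocab)
  keep <- !is.na(jj)
  Matrix::sparseMatrix(
    i = ii[keep], j = jj[keep], x = 1,
    dims = c(length(tokens), length(vocab))
  )
}

#' Train the reference bag-of-words relevance classifier
#'
#' Fits a ridge-penalized logistic regression (via glmnet) on unigram counts
#' of the training texts. This is the reference implementation of the
#' pluggable relevance-classifier interface: any object with a
#' [classify()] method can replace it downstream (e.g. an external
#' transformer-backed model), no other code changes required.
#'
#' @param posts Data frame with columns `text` and `label`
#'   (`"relevant"`/`"irrelevant"`); both labels must be present.
#' @param lambda Ridge penalty.
#' @param min_count Drop vocabulary seen fewer than this many times.
#' @param seed Seed (the fit is deterministic; the seed guards any future
#'   stochastic components of the interface).
#' @return An object of class `relevance_classifier`.
#' @export
train_classifier <- function(posts, lambda = 1e-3, min_count = 1L, seed = 1L) {
  if (!all(c("text", "label") %in% names(posts))) {
    abort("`posts` must have columns `text` and `label`.")
  }
  lab <- posts$label
  if (any(is.na(lab))) abort("training posts must all be labeled.")
  lev <- c("irrelevant", "relevant")
  if (!all(lab %in% lev)) abort("labels must be 'relevant' or 'irrelevant'.")
  if (length(unique(lab)) < 2L) {
    abort("single-class training set: both labels must be present.")
  }
  tokens <- tokenize_text(posts$text)
  vocab <- table(unlist(tokens))
  vocab <- names(vocab[vocab >= min_count])
  if (!length(vocab)) abort("training corpus has an empty vocabulary.")
  x <- build_dtm(tokens, vocab)
  y <- as.integer(lab == "relevant")
  fit <- withr::with_seed(seed, glmnet::glmnet(
    x, y,
    family = "binomial", alpha = 0,
    lambda = c(10 * lambda, lambda), standardize = FALSE
  ))
  beta <- as.numeric(coef(fit, s = lambda))
  structure(
    list(
      vocab = vocab,
      intercept = beta[1],
      weights = beta[-1],
      levels = lev,
      seed = as.integer(seed)
    ),
    class = "relevance_classifier"
  )
}

#' Classify post texts as allergy-relevant or not
#'
#' Generic entry point of the pluggable classifier interface.
#'
#' @param object A trained classifier.
#' @param text Character vector of post texts.
#' @param ... Passed to methods.
#' @return Character vector of `"relevant"`/`"irrelevant"` labels.
#' @export
classify <- function(object, text, ...) UseMethod("classify")

#' @rdname classify
#' @export
classify.relevance_classifier <- function(object, text, ...) {
  if (!length(text)) return(character())
  x <- build_dtm(tokenize_text(text), object$vocab)
  eta <- object$intercept + as.numeric(x %*% object$weights)
  ifelse(eta > 0, "relevant", "irrelevant")
}

#' Two-stage post filter: keywords then classifier
#'
#' Reproduces the surveillance filtering pipeline: posts must first contain a
#' configured keyword/hashtag, and the survivors must then be classified
#' relevant. Posts failing the keyword stage never reach the classifier. The
#' counts discarded at each stage are recorded in the `discard_log` attribute
#' (also retrievable with [discard_log()]).
#'
#' @param posts Data frame with a `text` column.
#' @param terms A [term_list()].
#' @param classifier An object with a [classify()] method.
#' @return The retained rows of `posts`, with a `discard_log` attribute.
#' @export
filter_posts <- function(posts, terms, classifier) {
  if (!"text" %in% names(posts)) abort("`posts` must have a `text` column.")
  n0 <- nrow(posts)
  kw <- keyword_match(posts$text, terms)
  kept_kw <- posts[kw, , drop = FALSE]
  if (nrow(kept_kw)) {
    pred <- classify(classifier, kept_kw$text)
    out <- kept_kw[pred == "relevant", , drop = FALSE]
  } else {
    out <- kept_kw
  }
  log <- tibble(
    stage = c("input", "keyword_match", "classifier_relevant"),
    n_in = c(n0, n0, nrow(kept_kw)),
    n_out = c(n0, nrow(kept_kw), nrow(out)),
    n_discarded = c(0L, n0 - nrow(kept_kw), nrow(kept_kw) - nrow(out))
  )
  attr(out, "discard_log") <- log
  out
}

#' @rdname filter_posts
#' @param x An object carrying a `discard_log` attribute.
#' @export
discard_log <- function(x) attr(x, "discard_log")

#' Confusion-matrix metrics for a relevance classifier
#'
#' Computes accuracy, precision, and recall with `"relevant"` as the positive
#' class. A metric whose denominator is zero is undefined and reported as
#' `NA`, never as 0.
#'
#' @param predictions,truth Equal-length character vectors of
#'   `"relevant"`/`"irrelevant"` labels.
#' @return One-row tibble: tp, fp, fn, tn, accuracy, precision, recall.
#' @export
evaluate_classifier <- function(predictions, truth) {
  if (length(predictions) != length(truth)) {
    abort("`predictions` and `truth` must have equal length.")
  }
  tp <- sum(predictions == "relevant" & truth == "relevant")
  fp <- sum(predictions == "relevant" & truth == "irrelevant")
  fn <- sum(predictions == "irrelevant" & truth == "relevant")
  tn <- sum(predictions == "irrelevant" & truth == "irrelevant")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    accuracy = ratio(tp + tn, tp + fp + fn + tn),
    precision = ratio(tp, tp + fp),
    recall = ratio(tp, tp + fn)
  )
}
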