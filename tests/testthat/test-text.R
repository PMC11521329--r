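test_that("keyword pre-filter matches on word boundaries and hashtags", {
  terms <- default_terms()
  expect_true(keyword_match("My allergies are really bad today!!", terms))
  # an irrelevant post can still pass the pre-filter; the classifier must
  # reject it later
  expect_true(keyword_match("Gluten and Allergy Free expo", terms))
  expect_false(keyword_match("nice weather today", terms))
  expect_false(keyword_match("", terms))
  expect_false(keyword_match(NA_character_, terms))
  # word boundaries: substrings do not match
  expect_false(keyword_match("allergyproof paint sale", term_list("allergy")))
  expect_true(keyword_match("hay fever season", default_terms()))
  expect_true(keyword_match("ugh #pollen everywhere", term_list("nothing", hashtags = "#pollen")))
  expect_false(keyword_match("pollen count high", term_list("nothing", hashtags = "#pollen")))
})

test_that("enlarging the term list never decreases the keyword-pass count", {
  cfg <- sim_config(n_regions = 1, n_days = 120, seed = 8)
  posts <- generate_posts(generate_latent(cfg), cfg)
  small <- term_list(c("allergies", "pollen"))
  big <- term_list(c("allergies", "pollen", "sneeze", "sneezing", "allergy"))
  expect_lte(sum(keyword_match(posts$text, small)), sum(keyword_match(posts$text, big)))
})

test_that("classifier separates disjoint vocabularies and is deterministic", {
  corpus <- separable_corpus(500, seed = 4)
  train <- corpus[c(1:350, 501:850), ]
  test <- corpus[c(351:500, 851:1000), ]
  cl <- train_classifier(train, seed = 9)
  pred <- classify(cl, test$text)
  m <- evaluate_classifier(pred, test$label)
  expect_gte(m$accuracy, 0.95)
  cl2 <- train_classifier(train, seed = 9)
  expect_identical(classify(cl2, test$text), pred)
  expect_error(
    train_classifier(corpus[1:500, ]),
    "single-class"
  )
})

test_that("classifier beats the all-relevant baseline on a contaminated corpus", {
  cfg <- sim_config(n_regions = 2, n_days = 300, seed = 21, contamination_rate = 0.2)
  posts <- generate_posts(generate_latent(cfg), cfg)
  posts <- posts[keyword_match(posts$text, cfg$terms), ]
  idx <- withr::with_seed(5, sample(nrow(posts), 4000))
  train <- posts[idx[1:2000], ]
  test <- posts[idx[2001:4000], ]
  cl <- train_classifier(train, seed = 1)
  m <- evaluate_classifier(classify(cl, test$text), test$label)
  baseline <- mean(test$label == "relevant")
  expect_gt(m$accuracy, baseline)
})

test_that("filter_posts applies keyword stage before classifier and keeps books", {
  corpus <- separable_corpus(200, seed = 6)
  cl <- train_classifier(corpus, seed = 2)
  terms <- term_list(c("pollen", "sneezing", "congested", "antihistamine", "itchy"))

  empty <- filter_posts(corpus[0, ], terms, cl)
  expect_equal(nrow(empty), 0)
  expect_equal(discard_log(empty)$n_out, c(0L, 0L, 0L))

  out <- filter_posts(corpus, terms, cl)
  log <- discard_log(out)
  kw <- keyword_match(corpus$text, terms)
  expect_equal(log$n_out[2], sum(kw))
  # retained = classifier-relevant among keyword passes = TP + FP there
  preds <- classify(cl, corpus$text[kw])
  truth <- corpus$label[kw]
  m <- evaluate_classifier(preds, truth)
  expect_equal(nrow(out), m$tp + m$fp)
  # output is a subset of keyword-matching posts
  expect_true(all(out$text %in% corpus$text[kw]))
})

test_that("classifier metrics follow the confusion identities", {
  all_right <- evaluate_classifier(rep("relevant", 5), rep("relevant", 5))
  expect_equal(all_right$accuracy, 1)
  expect_equal(all_right$recall, 1)

  pred <- c(rep("relevant", 10), rep("irrelevant", 10))
  truth <- c(rep("relevant", 9), "irrelevant", "relevant", rep("irrelevant", 9))
  m <- evaluate_classifier(pred, truth)
  expect_equal(m$tp, 9)
  expect_equal(m$fp, 1)
  expect_equal(m$fn, 1)
  expect_equal(m$tn, 9)
  expect_equal(m$accuracy, 0.9)
  expect_equal(m$precision, 0.9)
  expect_equal(m$recall, 0.9)

  # no positive predictions: precision undefined, not zero
  none <- evaluate_classifier(rep("irrelevant", 4), c("relevant", rep("irrelevant", 3)))
  expect_true(is.na(none$precision))
  expect_false(isTRUE(none$precision == 0))

  # permutation invariance over paired samples
  perm <- withr::with_seed(3, sample(length(pred)))
  expect_equal(evaluate_classifier(pred[perm], truth[perm]), m)

  expect_error(evaluate_classifier("relevant", c("relevant", "relevant")), "equal length")
})
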