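test_that("keyword matching is whole-token and multi-label", {
  loc <- default_location_lexicon()
  cp <- match_keywords(c("vape", "in", "my", "bedroom"), loc)
  expect_identical(cp$categories, "Living space")
  expect_identical(cp$matched_keywords, list("Living space" = "bedroom"))

  cp2 <- match_keywords(c("vape", "at", "school", "before", "work"), loc)
  expect_setequal(cp2$categories, c("School", "Workplace"))

  # "car" must not fire on "care" or "carpet"
  cp3 <- match_keywords(c("care", "carpet"), loc)
  expect_length(cp3$categories, 0)
})

test_that("multi-word phrases match contiguously after lemmatization", {
  vap <- default_vaping_lexicon()
  hit <- match_keywords(normalize_post("loving my new e-cigarettes!"), vap)
  expect_true("e cigarette" %in% unlist(hit$matched_keywords))
  gap <- match_keywords(c("e", "major", "cigarette"), vap)
  expect_false("e cigarette" %in% unlist(gap$matched_keywords))
})

test_that("the analytic sample requires both a vaping term and a location keyword", {
  rc <- mini_corpus(c("vaping all day long",              # no location
                      "sitting at school all day",        # no vaping term
                      "vaping at school all day"))        # both
  cl <- classify_corpus(rc)
  expect_identical(cl$post_id, "p003")
  expect_identical(cl$categories[[1]], "School")
})

test_that("production matcher equals the brute-force positional scan", {
  for (seed in c(101, 202, 303)) {
    rc <- generate_corpus(corpus_spec(400, seed = seed))
    prod <- classify_corpus(rc)
    oracle <- oracle_classify(rc)
    expect_equal(nrow(prod), length(oracle))
    oracle_ids <- vapply(oracle, `[[`, character(1), "post_id")
    expect_setequal(prod$post_id, oracle_ids)
    o <- oracle[match(prod$post_id, oracle_ids)]
    for (i in seq_len(nrow(prod))) {
      expect_setequal(prod$categories[[i]], o[[i]]$categories)
      for (cat in prod$categories[[i]]) {
        expect_setequal(prod$matched_keywords[[i]][[cat]],
                        o[[i]]$matched_keywords[[cat]])
      }
    }
  }
})

test_that("recovered category sets equal planted sets on clean corpora", {
  for (seed in c(7, 77)) {
    rc <- generate_corpus(corpus_spec(
      600, frac_retweet = 0, frac_non_english = 0, frac_bot = 0,
      frac_high_freq = 0, frac_duplicate = 0, frac_promotional = 0,
      seed = seed))
    cl <- classify_corpus(rc)
    expect_equal(nrow(cl), nrow(rc))
    planted <- truth_categories(rc)[match(cl$post_id, rc$post_id)]
    for (i in seq_len(nrow(cl))) {
      expect_setequal(cl$categories[[i]], planted[[i]])
    }
  }
})

test_that("adding a keyword never removes a category from any assignment", {
  rc <- generate_corpus(corpus_spec(300, seed = 41))
  loc <- default_location_lexicon()
  before <- classify_corpus(rc, location_lexicon = loc)
  loc$entries$Stores <- c(loc$entries$Stores, "friend")  # filler word
  after <- classify_corpus(rc, location_lexicon = loc)
  expect_true(all(before$post_id %in% after$post_id))
  for (i in seq_len(nrow(before))) {
    j <- match(before$post_id[i], after$post_id)
    expect_true(all(before$categories[[i]] %in% after$categories[[j]]))
  }
})

test_that("classification is independent of record order", {
  rc <- generate_corpus(corpus_spec(300, seed = 53))
  cl1 <- classify_corpus(rc)
  set.seed(1)
  shuffled <- rc[sample.int(nrow(rc)), ]
  cl2 <- classify_corpus(shuffled)
  expect_setequal(cl1$post_id, cl2$post_id)
  m <- match(cl1$post_id, cl2$post_id)
  for (i in seq_len(nrow(cl1))) {
    expect_setequal(cl1$categories[[i]], cl2$categories[[m[i]]])
  }
})

test_that("first_match mode assigns one category by lexicon order", {
  rc <- mini_corpus("vape at school before work every day")
  cl <- classify_corpus(rc, mode = "first_match")
  expect_identical(cl$categories[[1]], "School")
  expect_named(cl$matched_keywords[[1]], "School")
})

test_that("hashtag keywords only fire when keep_hashtag_words is on", {
  rc <- mini_corpus("vaping at the #party")
  expect_equal(nrow(classify_corpus(rc)), 0)
  cl <- classify_corpus(rc, keep_hashtag_words = TRUE)
  expect_identical(cl$categories[[1]], "Social venues")
})
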