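zero_contamination <- function(n, mixture, seed, multi_label_rate = 0.106) {
  corpus_spec(n, frac_retweet = 0, frac_non_english = 0, frac_bot = 0,
              frac_high_freq = 0, frac_duplicate = 0, frac_promotional = 0,
              category_mixture = mixture, seed = seed,
              multi_label_rate = multi_label_rate)
}

test_that("a degenerate single-category spec yields all-clean single-category posts", {
  rc <- generate_corpus(zero_contamination(
    100, c("Social venues" = 1.0), seed = 7, multi_label_rate = 0))
  expect_equal(nrow(rc), 100)
  expect_true(all(truth_kinds(rc) == "clean"))
  cl <- classify_corpus(rc)
  expect_equal(nrow(cl), 100)
  expect_true(all(vapply(cl$categories, identical, TRUE, "Social venues")))
})

test_that("planted contaminant counts equal the drawn assignment for any seed", {
  spec <- corpus_spec(1000, frac_retweet = 0.2, seed = 1)
  rc <- generate_corpus(spec)
  kinds <- truth_kinds(rc)
  expect_equal(sum(kinds == "retweet"), 200)
  # label conservation across several seeds
  for (seed in c(2, 3)) {
    rc <- generate_corpus(corpus_spec(1000, seed = seed))
    kinds <- table(truth_kinds(generate_corpus(corpus_spec(1000, seed = seed))))
    expect_equal(as.integer(kinds[c("retweet", "non_english", "bot",
                                    "high_freq", "duplicate",
                                    "promotional")]),
                 c(100L, 100L, 50L, 50L, 50L, 50L))
    expect_equal(sum(kinds), 1000L)
  }
})

test_that("identical specs produce byte-identical corpora", {
  a <- generate_corpus(corpus_spec(800, seed = 99))
  b <- generate_corpus(corpus_spec(800, seed = 99))
  p1 <- withr::local_tempfile(fileext = ".jsonl")
  p2 <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(a, p1); write_corpus(b, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("clean posts carry no contaminant markers", {
  rc <- generate_corpus(corpus_spec(2000, seed = 19))
  kinds <- truth_kinds(rc)
  clean <- rc[kinds == "clean", ]
  expect_false(any(startsWith(clean$text, "RT @")))
  expect_true(all(clean$lang == "en"))
  expect_false(any(clean$is_retweet))
  expect_false(any(grepl("https?://", clean$text)))
  bot_accounts <- unique(rc$account_id[kinds == "bot"])
  expect_length(intersect(clean$account_id, bot_accounts), 0)
})

test_that("the filler vocabulary shares no lemma with either lexicon", {
  filler <- vapescope:::filler_vocabulary(default_vaping_lexicon(),
                                          default_location_lexicon())
  reserved <- c(vapescope:::lexicon_tokens(default_vaping_lexicon()),
                vapescope:::lexicon_tokens(default_location_lexicon()))
  expect_length(intersect(lemmatize(filler), reserved), 0)
  expect_identical(filler, vapescope:::.vs_filler_vocab)
})

test_that("duplicates are exact later copies of clean posts under fresh ids", {
  rc <- generate_corpus(corpus_spec(2000, seed = 43))
  kinds <- truth_kinds(rc)
  dups <- which(kinds == "duplicate")
  expect_gt(length(dups), 0)
  for (i in dups) {
    src_id <- rc$truth_labels[[i]]$source_post_id
    j <- match(src_id, rc$post_id)
    expect_identical(rc$text[i], rc$text[j])
    expect_gt(as.numeric(rc$created_at[i]), as.numeric(rc$created_at[j]))
    expect_false(rc$post_id[i] == src_id)
  }
})

test_that("mixture_truth reports label-only prevalence", {
  rc <- generate_corpus(zero_contamination(
    100, c("Living space" = 1.0), seed = 3, multi_label_rate = 0))
  tr <- mixture_truth(rc)
  expect_equal(tr$n_total, 100L)
  expect_equal(tr$rows$percent[tr$rows$category == "Living space"], 100)

  # realized proportions of a two-category mixture hover near the target
  rc2 <- generate_corpus(zero_contamination(
    4000, c("School" = 0.5, "Workplace" = 0.5), seed = 11,
    multi_label_rate = 0))
  tr2 <- mixture_truth(rc2)
  p <- tr2$rows$n_posts / tr2$n_total
  expect_true(all(abs(p - 0.5) < 3 * sqrt(0.25 / 4000)))

  # empty clean subset
  allrt <- generate_corpus(corpus_spec(
    50, frac_retweet = 1, frac_non_english = 0, frac_bot = 0,
    frac_high_freq = 0, frac_duplicate = 0, frac_promotional = 0, seed = 2))
  tr3 <- mixture_truth(allrt)
  expect_equal(tr3$n_total, 0L)
  expect_equal(nrow(tr3$rows), 0L)

  unlabeled <- mini_corpus("no labels here")
  expect_error(mixture_truth(unlabeled), "truth_labels")
})

test_that("invalid specs are rejected", {
  expect_error(corpus_spec(100, frac_retweet = 1.2), "\\[0, 1\\]")
  expect_error(corpus_spec(100, frac_retweet = 0.6, frac_non_english = 0.6),
               "sum above 1")
  expect_error(corpus_spec(100, category_mixture = c(A = 0.5, B = 0.4)),
               "sum to 1")
  expect_error(corpus_spec(100, multi_label_rate = 2), "multi_label_rate")
})
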