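test_that("retweets are removed by flag or RT-prefix", {
  rc <- mini_corpus(c(sprintf("post %d", 1:7), sprintf("RT @x: copy %d", 1:3)),
                    is_retweet = c(rep(FALSE, 7), rep(TRUE, 3)))
  res <- filter_retweets(rc)
  expect_equal(nrow(res$records), 7)
  expect_equal(res$report$n_removed, 3)

  # prefix inference when the flag is absent
  rc2 <- mini_corpus(c("RT @y: hi there", "plain post"), is_retweet = NA)
  expect_equal(filter_retweets(rc2)$records$text, "plain post")

  all_rt <- mini_corpus(sprintf("RT @z: %d", 1:4), is_retweet = TRUE)
  res3 <- filter_retweets(all_rt)
  expect_equal(nrow(res3$records), 0)
  expect_equal(res3$report$n_removed, res3$report$n_in)
})

test_that("language filter keeps allowed tags and falls back to detection", {
  rc <- mini_corpus(c("I am at the game with you",
                      "el tiempo es bueno hoy en la ciudad",
                      "the weather is nice and it is for you"),
                    lang = c("en", "es", "und"))
  res <- filter_language(rc, filter_config())
  expect_setequal(res$records$post_id, c("p001", "p003"))
  expect_equal(res$report$n_removed, 1)
  expect_identical(detect_language("el tiempo es bueno para la gente"), "es")
  expect_identical(detect_language("!!!"), "und")
})

test_that("account stats arithmetic matches the day-span definition", {
  base <- as.POSIXct("2018-02-01 12:00:00", tz = "UTC")
  rc <- tweet_corpus(sprintf("p%02d", 1:10), "acct", sprintf("text %d", 1:10),
                     created_at = base + rep(86400 * 0:4, 2))
  st <- compute_account_stats(rc)
  expect_equal(st$n_posts, 10L)
  expect_equal(st$active_days, 5L)
  expect_equal(st$posts_per_day, 2.0)

  same <- tweet_corpus(c("a", "b"), "acct", c("x", "y"), created_at = base)
  expect_equal(compute_account_stats(same)$active_days, 1L)

  rc2 <- generate_corpus(corpus_spec(500, seed = 3))
  expect_equal(sum(compute_account_stats(rc2)$n_posts), nrow(rc2))
})

test_that("bot flagging respects the rate threshold and the pluggable scorer", {
  st <- tibble::tibble(account_id = c("slow", "fast"),
                       n_posts = c(10L, 60L), active_days = c(1L, 1L),
                       posts_per_day = c(10, 60))
  cfg <- filter_config(bot_rate_threshold = 50)
  expect_identical(flag_bot_accounts(st, cfg), "fast")
  custom <- filter_config(bot_scorer = function(s) s$n_posts < 20)
  expect_identical(flag_bot_accounts(st, custom), "slow")
  expect_error(flag_bot_accounts(st[0, ], cfg), "empty")
})

test_that("high-frequency flagging matches the mean + k*SD hand computation", {
  mk_stats <- function(rates) tibble::tibble(
    account_id = sprintf("a%02d", seq_along(rates)),
    n_posts = as.integer(rates), active_days = 1L, posts_per_day = rates)
  cfg <- filter_config(bot_rate_threshold = 1e6, high_freq_multiplier = 2)
  rates <- c(1, 1, 1, 1, 1, 100)
  thr <- mean(rates) + 2 * sqrt(mean((rates - mean(rates))^2))
  expect_identical(flag_high_frequency_accounts(mk_stats(rates), cfg),
                   mk_stats(rates)$account_id[rates > thr])
  expect_length(flag_high_frequency_accounts(mk_stats(rates), cfg), 1)

  # degenerate: equal rates, SD = 0, strict inequality flags nobody
  expect_length(flag_high_frequency_accounts(mk_stats(rep(5, 10)), cfg), 0)
  expect_error(flag_high_frequency_accounts(mk_stats(5), cfg), "at least 2")

  # bot-rate accounts are excluded from the mean/SD baseline
  cfg2 <- filter_config(bot_rate_threshold = 50, high_freq_multiplier = 2)
  rates2 <- c(rep(1, 20), 20, 500)   # 500 is bot-range, 20 is heavy
  flagged <- flag_high_frequency_accounts(mk_stats(rates2), cfg2)
  expect_identical(flagged, mk_stats(rates2)$account_id[21])
})

test_that("duplicate filter keeps the earliest copy only", {
  base <- as.POSIXct("2018-05-01", tz = "UTC")
  rc <- tweet_corpus(c("a", "b", "c", "d"), "u",
                     c("same text", "same  text", "same text", "other"),
                     created_at = base + c(300, 100, 200, 0))
  res <- filter_duplicates(rc)
  expect_setequal(res$records$post_id, c("b", "d"))
  expect_equal(res$report$n_removed, 2)

  nodup <- mini_corpus(sprintf("unique %d", 1:5))
  expect_equal(filter_duplicates(nodup)$records$post_id, nodup$post_id)
})

test_that("promotional filter requires a marker term (and a URL when configured)", {
  rc <- mini_corpus(c("20% off juul pods today http://x.co",
                      "big sale on mods https://deals.example/1",
                      "I turned the tv off today",
                      "clean vape post at home"))
  res <- filter_promotional(rc, filter_config())
  expect_setequal(res$records$post_id, c("p003", "p004"))
  res2 <- filter_promotional(rc, filter_config(promo_requires_url = FALSE))
  expect_setequal(res2$records$post_id, "p004")
})

test_that("each cascade stage removes exactly its planted contaminant set", {
  rc <- generate_corpus(corpus_spec(4000, seed = 17))
  kinds <- truth_kinds(rc)
  cfg <- filter_config()
  stage_kind <- c(retweet = "retweet", language = "non_english",
                  bot = "bot", high_frequency = "high_freq",
                  duplicate = "duplicate", promotional = "promotional")
  res <- run_filter_cascade(rc, cfg)
  # reconstruct per-stage removals from the telescoping survivor sets
  current <- rc
  stages <- list(filter_retweets,
                 function(r) filter_language(r, cfg),
                 function(r) vapescope:::filter_bots(r, cfg),
                 function(r) vapescope:::filter_high_frequency(r, cfg),
                 filter_duplicates,
                 function(r) filter_promotional(r, cfg))
  for (i in seq_along(stages)) {
    step <- stages[[i]](current)
    removed <- setdiff(current$post_id, step$records$post_id)
    planted <- rc$post_id[kinds == stage_kind[[step$report$stage]]]
    expect_setequal(removed, planted)
    current <- step$records
  }
  expect_setequal(current$post_id, rc$post_id[kinds == "clean"])
})

test_that("filters are contractions, idempotent, and the cascade telescopes", {
  rc <- generate_corpus(corpus_spec(2000, seed = 23))
  cfg <- filter_config()
  filters <- list(filter_retweets,
                  function(r) filter_language(r, cfg),
                  function(r) vapescope:::filter_bots(r, cfg),
                  function(r) vapescope:::filter_high_frequency(r, cfg),
                  filter_duplicates,
                  function(r) filter_promotional(r, cfg))
  for (f in filters) {
    once <- f(rc)
    expect_true(all(once$records$post_id %in% rc$post_id))
    twice <- f(once$records)
    expect_equal(twice$report$n_removed, 0)
  }
  res <- run_filter_cascade(rc, cfg)
  expect_equal(res$reports$n_in[-1], res$reports$n_out[-6])
  expect_equal(res$reports$n_in[1] - sum(res$reports$n_removed),
               res$reports$n_out[6])
})

test_that("the survivor set is invariant under filter-stage permutations", {
  rc <- generate_corpus(corpus_spec(3000, seed = 29))
  cfg <- filter_config()
  stages <- list(filter_retweets,
                 function(r) filter_language(r, cfg),
                 function(r) vapescope:::filter_bots(r, cfg),
                 function(r) vapescope:::filter_high_frequency(r, cfg),
                 filter_duplicates,
                 function(r) filter_promotional(r, cfg))
  reference <- run_filter_cascade(rc, cfg)$records$post_id
  set.seed(31)
  perms <- c(list(6:1), lapply(1:4, function(i) sample(6)))
  for (perm in perms) {
    current <- rc
    for (i in perm) current <- stages[[i]](current)$records
    expect_setequal(current$post_id, reference)
  }
})
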