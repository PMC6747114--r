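# The exclusion cascade: retweets -> non-English -> bot accounts ->
# high-frequency accounts -> exact duplicates -> promotional posts.
# Every filter is a contraction (output is a subset of its input) and
# idempotent, and returns a per-stage attrition report.

#' Filter-cascade configuration
#'
#' @param allowed_langs Language tags kept by the language filter.
#' @param bot_rate_threshold Posting rate (posts/day) at or above which an
#'   account is treated as a bot. The published bot classifiers are
#'   proprietary; this reproducible rate heuristic is the pluggable default
#'   (see `bot_scorer`).
#' @param high_freq_multiplier `k` in the `mean + k * SD` rule for
#'   abnormally high-frequency accounts (population SD over per-account
#'   daily rates, computed after excluding bot-rate accounts).
#' @param promo_terms Lowercase promotional marker terms.
#' @param promo_requires_url Must a promotional post also contain a URL?
#' @param bot_scorer Optional function `(stats) -> logical` replacing the
#'   rate heuristic; receives the [compute_account_stats()] tibble.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(allowed_langs = "en",
                          bot_rate_threshold = 50,
                          high_freq_multiplier = 2,
                          promo_terms = default_promo_terms(),
                          promo_requires_url = TRUE,
                          bot_scorer = NULL) {
  assert_that(length(allowed_langs) > 0, "allowed_langs must be nonempty")
  assert_that(is.finite(bot_rate_threshold) && bot_rate_threshold > 0,
              "bot_rate_threshold must be a positive finite rate")
  assert_that(is.finite(high_freq_multiplier) && high_freq_multiplier > 0,
              "high_freq_multiplier must be positive and finite")
  structure(list(allowed_langs = allowed_langs,
                 bot_rate_threshold = bot_rate_threshold,
                 high_freq_multiplier = high_freq_multiplier,
                 promo_terms = trimws(tolower(promo_terms)),
                 promo_requires_url = isTRUE(promo_requires_url),
                 bot_scorer = bot_scorer),
            class = "filter_config")
}

#' Default promotional marker terms
#' @return Character vector of lowercase terms.
#' @export
default_promo_terms <- function() {
  c("sale", "discount", "promo", "coupon", "deal", "giveaway",
    "off", "free", "code", "buy")
}

stage_report <- function(stage, n_in, n_out) {
  tibble::tibble(stage = stage, n_in = n_in,
                 n_removed = n_in - n_out, n_out = n_out)
}

apply_mask <- function(records, keep, stage) {
  list(records = records[keep, , drop = FALSE],
       report = stage_report(stage, nrow(records), sum(keep)))
}

#' Remove retweets
#'
#' A record is a retweet if `is_retweet` is `TRUE` or, when the flag is
#' missing, if its text starts with `"RT @"`.
#'
#' @param records A corpus tibble.
#' @return List with `records` (kept rows) and `report` (one-row attrition
#'   tibble: stage, n_in, n_removed, n_out).
#' @export
filter_retweets <- function(records) {
  rt <- records$is_retweet %in% TRUE | startsWith(records$text, "RT @")
  apply_mask(records, !rt, "retweet")
}

.vs_stopword_banks <- list(
  en = c("the", "a", "an", "and", "of", "to", "in", "is", "it", "you",
         "that", "he", "was", "for", "on", "are", "with", "at", "my"),
  es = c("el", "la", "los", "las", "de", "que", "y", "en", "un", "una",
         "es", "no", "con", "por", "para", "hoy", "gracias"),
  fr = c("le", "la", "les", "de", "que", "et", "en", "un", "une", "est",
         "ne", "pas", "avec", "pour", "je", "merci"),
  de = c("der", "die", "das", "und", "ein", "eine", "ist", "nicht", "mit",
         "heute", "den", "ich", "zu", "danke")
)

#' Heuristic language identification fallback
#'
#' Scores lowercase tokens against small bundled stopword banks (en, es, fr,
#' de) and returns the best-scoring language, or `"und"` when no bank term
#' occurs. Used only for records whose stream `lang` tag is missing or
#' `"und"`; tagged records are trusted as-is.
#'
#' @param text Character vector.
#' @return Character vector of language codes.
#' @export
detect_language <- function(text) {
  toks <- stringi::stri_split_regex(
    stringi::stri_trans_tolower(text), "[^\\p{L}]+", omit_empty = TRUE)
  vapply(toks, function(t) {
    if (!length(t)) return("und")
    scores <- vapply(.vs_stopword_banks,
                     function(bank) sum(t %in% bank), numeric(1))
    if (max(scores) == 0) "und" else names(which.max(scores))
  }, character(1))
}

#' Remove non-English posts
#'
#' Keeps records whose `lang` tag is in `allowed_langs`; records with an
#' unknown or missing tag are passed to [detect_language()] and kept only if
#' identified as allowed.
#'
#' @param records A corpus tibble.
#' @param config A [filter_config()].
#' @return List with `records` and `report`.
#' @export
filter_language <- function(records, config = filter_config()) {
  lang <- records$lang
  unknown <- is.na(lang) | lang == "" | lang == "und"
  if (any(unknown)) lang[unknown] <- detect_language(records$text[unknown])
  base <- sub("-.*$", "", lang)
  apply_mask(records, base %in% config$allowed_langs, "language")
}

#' Per-account posting statistics
#'
#' `active_days` is the inclusive calendar-day span from an account's first
#' to last post (minimum 1); `posts_per_day = n_posts / active_days`.
#'
#' @param records A corpus tibble.
#' @return Tibble with `account_id`, `n_posts`, `active_days`,
#'   `posts_per_day`, one row per distinct account.
#' @export
compute_account_stats <- function(records) {
  dplyr::summarise(
    dplyr::group_by(tibble::tibble(account_id = records$account_id,
                                   day = as.Date(records$created_at)),
                    .data$account_id),
    n_posts = dplyr::n(),
    active_days = pmax(as.integer(max(.data$day) - min(.data$day)) + 1L, 1L),
    posts_per_day = .data$n_posts / .data$active_days,
    .groups = "drop"
  )
}

#' Flag bot accounts
#'
#' Default heuristic: accounts with `posts_per_day >=` the configured bot
#' rate threshold. A custom scorer supplied via `filter_config(bot_scorer=)`
#' replaces the heuristic entirely.
#'
#' @param stats Output of [compute_account_stats()]; must be nonempty.
#' @param config A [filter_config()].
#' @return Character vector of flagged account ids.
#' @export
flag_bot_accounts <- function(stats, config = filter_config()) {
  assert_that(nrow(stats) > 0, "account stats are empty")
  if (!is.null(config$bot_scorer)) {
    flagged <- config$bot_scorer(stats)
    assert_that(is.logical(flagged) && length(flagged) == nrow(stats),
                "bot_scorer must return one logical per account")
    return(stats$account_id[flagged])
  }
  stats$account_id[stats$posts_per_day >= config$bot_rate_threshold]
}

#' Flag abnormally high-frequency accounts
#'
#' Flags accounts with `posts_per_day > mean + k * SD`, where the mean and
#' population SD are computed over per-account daily rates after excluding
#' accounts at or above the bot rate threshold (bots would otherwise inflate
#' the scale and mask heavy posters). The inequality is strict, so a
#' degenerate corpus where every account posts at the same rate flags
#' nobody.
#'
#' @param stats Output of [compute_account_stats()]; needs >= 2 accounts.
#' @param config A [filter_config()].
#' @return Character vector of flagged account ids.
#' @export
flag_high_frequency_accounts <- function(stats, config = filter_config()) {
  assert_that(nrow(stats) >= 2,
              "high-frequency flagging needs at least 2 accounts")
  eligible <- stats[stats$posts_per_day < config$bot_rate_threshold, ,
                    drop = FALSE]
  if (nrow(eligible) < 2) return(character(0))
  x <- eligible$posts_per_day
  sd_pop <- sqrt(mean((x - mean(x))^2))
  thr <- mean(x) + config$high_freq_multiplier * sd_pop
  eligible$account_id[x > thr]
}

filter_bots <- function(records, config = filter_config()) {
  if (nrow(records) == 0) return(apply_mask(records, logical(0), "bot"))
  flagged <- flag_bot_accounts(compute_account_stats(records), config)
  apply_mask(records, !records$account_id %in% flagged, "bot")
}

filter_high_frequency <- function(records, config = filter_config()) {
  if (nrow(records) < 2) {
    return(apply_mask(records, rep(TRUE, nrow(records)), "high_frequency"))
  }
  stats <- compute_account_stats(records)
  flagged <- if (nrow(stats) >= 2) {
    flag_high_frequency_accounts(stats, config)
  } else character(0)
  apply_mask(records, !records$account_id %in% flagged, "high_frequency")
}

#' Remove exact-duplicate posts
#'
#' Among records sharing identical whitespace-normalized text, keeps the
#' earliest by `created_at` (ties broken by `post_id`); later copies are
#' removed. Detection is text-exact, not fuzzy.
#'
#' @param records A corpus tibble.
#' @return List with `records` and `report`.
#' @export
filter_duplicates <- function(records) {
  key <- stringi::stri_trim_both(
    stringi::stri_replace_all_regex(records$text, "\\s+", " "))
  ord <- order(records$created_at, records$post_id)
  dup_in_ord <- duplicated(key[ord])
  keep <- rep(TRUE, nrow(records))
  keep[ord] <- !dup_in_ord
  apply_mask(records, keep, "duplicate")
}

.vs_url_detect_re <- "(?i)(https?://|www\\.|\\bt\\.co/)"

#' Remove promotional posts
#'
#' A record is promotional when its lowercased text contains at least one
#' promotional marker term as a whole word and, if `promo_requires_url`,
#' also contains a URL.
#'
#' @param records A corpus tibble.
#' @param config A [filter_config()].
#' @return List with `records` and `report`.
#' @export
filter_promotional <- function(records, config = filter_config()) {
  if (length(config$promo_terms) == 0) {
    return(apply_mask(records, rep(TRUE, nrow(records)), "promotional"))
  }
  lowered <- stringi::stri_trans_tolower(records$text)
  pat <- paste0("\\b(", paste(stringi::stri_replace_all_regex(
    config$promo_terms, "([\\\\.^$|()\\[\\]{}*+?])", "\\\\$1"),
    collapse = "|"), ")\\b")
  promo <- stringi::stri_detect_regex(lowered, pat)
  if (config$promo_requires_url) {
    promo <- promo & stringi::stri_detect_regex(lowered, .vs_url_detect_re)
  }
  apply_mask(records, !promo, "promotional")
}

#' Run the full exclusion cascade
#'
#' Applies the six filters in fixed order: retweet, language, bot,
#' high-frequency, duplicate, promotional. Attrition reports chain: each
#' stage's `n_in` equals the previous stage's `n_out`.
#'
#' @param records A corpus tibble.
#' @param config A [filter_config()].
#' @return List with `records` (survivors) and `reports` (six-row attrition
#'   tibble).
#' @export
run_filter_cascade <- function(records, config = filter_config()) {
  stages <- list(
    function(r) filter_retweets(r),
    function(r) filter_language(r, config),
    function(r) filter_bots(r, config),
    function(r) filter_high_frequency(r, config),
    function(r) filter_duplicates(r),
    function(r) filter_promotional(r, config)
  )
  reports <- vector("list", length(stages))
  for (i in seq_along(stages)) {
    res <- stages[[i]](records)
    records <- res$records
    reports[[i]] <- res$report
  }
  list(records = records, reports = dplyr::bind_rows(reports))
}

#' @importFrom dplyr .data
NULL
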