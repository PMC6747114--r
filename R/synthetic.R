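# Synthetic tweet-corpus generator. Every post carries a ground-truth label
# (its contaminant kind, or "clean" plus the planted category set), so each
# downstream stage can be checked exactly. Contaminant kinds are mutually
# exclusive per post, resolved in the fixed priority order
# retweet > non-English > bot > high-frequency > duplicate > promotional.
#
# Rate structure (what makes stage recovery exact by construction):
#   * clean and low-rate contaminant posts are pooled into multi-post
#     accounts whose first/last posts are pinned to the period endpoints,
#     so their per-account daily rates are uniformly small;
#   * bot accounts emit ~bot_posts_per_day posts within one calendar day;
#   * high-frequency accounts emit ~high_freq_posts_per_day posts/day over
#     two days -- above the mean + k*SD rule, below the bot threshold.

.vs_filler_vocab <- c(
  "the", "a", "an", "and", "but", "with", "for", "about", "after", "before",
  "my", "your", "our", "his", "her", "their", "this", "that", "these", "it",
  "me", "you", "we", "they", "he", "she", "so", "just", "really", "very",
  "quite", "still", "again", "then", "now", "today", "tonight", "always",
  "never", "often", "sometimes", "here", "there", "everyone", "nobody",
  "friend", "buddy", "people", "thing", "stuff", "moment", "minute", "hour",
  "week", "month", "year", "feeling", "mood", "vibe", "honestly",
  "literally", "actually", "finally", "maybe", "probably", "definitely",
  "lol", "omg", "tbh", "smh", "yall", "gonna", "wanna", "kinda", "super",
  "weird", "crazy", "wild", "funny", "tired", "sleepy", "happy", "chill",
  "calm", "quiet", "loud", "good", "bad", "nice", "cool", "warm", "cold"
)

.vs_nonenglish_banks <- list(
  es = c("hola", "gracias", "siempre", "nunca", "amigo", "noche", "tiempo",
         "bueno", "ciudad", "hoy", "nada", "claro", "entonces", "porque"),
  fr = c("bonjour", "merci", "toujours", "jamais", "nuit", "temps", "ville",
         "rien", "bien", "alors", "peut", "voila", "ensemble", "demain"),
  de = c("hallo", "danke", "immer", "niemals", "nacht", "zeit", "stadt",
         "heute", "nichts", "gut", "also", "vielleicht", "morgen", "wieder")
)

.vs_promo_phrases <- c("20% off today only", "big sale this weekend",
                       "use discount code", "free shipping deal",
                       "buy one get one", "giveaway ends soon")

.vs_vaping_surfaces <- list(
  "vape" = c("vape", "vaping", "vapes", "Vaping", "VAPE"),
  "vaper" = c("vaper", "vapers"),
  "vapor" = c("vapor"), "vapour" = c("vapour"),
  "vaporizer" = c("vaporizer", "vaporizers"),
  "e cig" = c("e-cig", "e-cigs"), "ecig" = c("ecig", "ecigs"),
  "e cigarette" = c("e-cigarette", "e-cigarettes", "E-cigarette"),
  "ecigarette" = c("ecigarette"),
  "e liquid" = c("e-liquid", "e-liquids"), "eliquid" = c("eliquid"),
  "e juice" = c("e-juice"), "ejuice" = c("ejuice"),
  "juul" = c("juul", "JUUL", "juuling", "juuls"),
  "vape pen" = c("vape pen", "vape pens"),
  "vape juice" = c("vape juice"),
  "box mod" = c("box mod", "box mods"),
  "e hookah" = c("e-hookah"), "ehookah" = c("ehookah"),
  "nic salt" = c("nic salt", "nic salts"),
  "cloud chase" = c("cloud chasing", "cloud chase"),
  "atomizer" = c("atomizer", "atomizers"), "cartomizer" = c("cartomizer"),
  "clearomizer" = c("clearomizer"),
  "mod" = c("mod", "mods"), "squonk" = c("squonk", "squonking")
)

.vs_keyword_inflections <- list(
  drive = c("driving", "drove"), party = c("parties", "partying"),
  shop = c("shopping"), work = c("working"), church = c("churches"),
  class = c("classes"), bus = c("buses"), beach = c("beaches")
)

#' Default planted category mixture
#'
#' Eleven location categories with probabilities proportional to the
#' prevalences the surveillance literature reports for vaping-related posts
#' (social venues most common at ~18%, religious institutions rarest at
#' ~0.4%), normalized to sum to 1.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_category_mixture <- function() {
  w <- c("Social venues" = 17.9, "Living space" = 16.7, "Stores" = 15.9,
         "Modes of transportation" = 15.5, "School" = 14.9,
         "Workplace" = 11.9, "Healthcare offices" = 2.0, "Eateries" = 1.2,
         "Correctional facility" = 0.7, "Religious institutions" = 0.4,
         "Miscellaneous" = 13.5)
  w / sum(w)
}

#' Specification for a synthetic corpus
#'
#' Contamination fractions are resolved in the fixed priority order
#' retweet > non-English > bot > high-frequency > duplicate > promotional,
#' so every post gets exactly one contaminant kind or "clean". Defaults
#' emulate a keyword-collected stream: 10% retweets, 10% non-English, 5%
#' each of bot, high-frequency, duplicate and promotional posts, and a
#' clean remainder whose location-category mixture follows
#' [default_category_mixture()] with a 10.6% double-label rate.
#'
#' @param n_posts Total number of posts.
#' @param frac_retweet,frac_non_english,frac_bot,frac_high_freq,frac_duplicate,frac_promotional
#'   Contaminant fractions, each in `[0, 1]`, jointly summing to at most 1.
#' @param category_mixture Named probabilities over location categories
#'   (must sum to 1 within 1e-9).
#' @param multi_label_rate Probability a clean post receives a second,
#'   distinct planted category.
#' @param n_accounts Approximate number of clean-poster accounts (default:
#'   one per ~20 clean posts). Honored approximately: account sizes are kept
#'   uniform so that per-account posting rates are uniform, which is what
#'   makes high-frequency-stage recovery exact.
#' @param seed Integer seed; fully determines the corpus.
#' @param bot_posts_per_day Planted bot posting rate (posts/day).
#' @param high_freq_posts_per_day Planted heavy-poster rate (posts/day).
#' @return A list of class `corpus_spec`.
#' @export
corpus_spec <- function(n_posts,
                        frac_retweet = 0.10, frac_non_english = 0.10,
                        frac_bot = 0.05, frac_high_freq = 0.05,
                        frac_duplicate = 0.05, frac_promotional = 0.05,
                        category_mixture = default_category_mixture(),
                        multi_label_rate = 0.106,
                        n_accounts = NULL,
                        seed = 1L,
                        bot_posts_per_day = 60,
                        high_freq_posts_per_day = 12) {
  fracs <- c(retweet = frac_retweet, non_english = frac_non_english,
             bot = frac_bot, high_freq = frac_high_freq,
             duplicate = frac_duplicate, promotional = frac_promotional)
  assert_that(n_posts >= 0, "n_posts must be nonnegative")
  assert_that(all(fracs >= 0 & fracs <= 1),
              "contamination fractions must be in [0, 1]")
  assert_that(sum(fracs) <= 1 + 1e-12,
              "contamination fractions sum above 1")
  assert_that(abs(sum(category_mixture) - 1) <= 1e-9,
              "category_mixture must sum to 1")
  assert_that(!is.null(names(category_mixture)) &&
                all(nzchar(names(category_mixture))),
              "category_mixture must be named")
  assert_that(multi_label_rate >= 0 && multi_label_rate <= 1,
              "multi_label_rate must be in [0, 1]")
  assert_that(is.null(n_accounts) || n_accounts >= 1,
              "n_accounts must be >= 1")
  structure(list(n_posts = as.integer(n_posts), fracs = fracs,
                 category_mixture = category_mixture,
                 multi_label_rate = multi_label_rate,
                 n_accounts = n_accounts, seed = as.integer(seed),
                 bot_posts_per_day = bot_posts_per_day,
                 high_freq_posts_per_day = high_freq_posts_per_day),
            class = "corpus_spec")
}

#' @export
print.corpus_spec <- function(x, ...) {
  cat(sprintf("<corpus_spec: %d posts, seed %d, contamination %s>\n",
              x$n_posts, x$seed,
              paste(sprintf("%s=%.2f", names(x$fracs), x$fracs),
                    collapse = " ")))
  invisible(x)
}

# Candidate surface forms for a (lemma-form) keyword, kept only if they
# normalize back to exactly the keyword's token sequence.
keyword_surfaces <- function(kw) {
  cand <- unique(c(
    kw,
    paste0(toupper(substr(kw, 1, 1)), substr(kw, 2, nchar(kw))),
    paste0(kw, "s"),
    .vs_keyword_inflections[[kw]]
  ))
  target <- strsplit(kw, " ", fixed = TRUE)[[1]]
  ok <- vapply(cand, function(s) {
    identical(normalize_text(s)[[1]], target)
  }, logical(1))
  cand[ok]
}

validated_surface_table <- function(lex) {
  kws <- unique(unlist(lex$entries, use.names = FALSE))
  setNames(lapply(kws, keyword_surfaces), kws)
}

validated_vaping_surfaces <- function(vaping_lexicon) {
  terms <- unique(unlist(vaping_lexicon$entries, use.names = FALSE))
  setNames(lapply(terms, function(term) {
    cand <- unique(c(term, .vs_vaping_surfaces[[term]]))
    target <- strsplit(term, " ", fixed = TRUE)[[1]]
    cand[vapply(cand, function(s) {
      identical(normalize_text(s)[[1]], target)
    }, logical(1))]
  }), terms)
}

filler_vocabulary <- function(vaping_lexicon, location_lexicon,
                              promo_terms = default_promo_terms()) {
  reserved <- c(lexicon_tokens(vaping_lexicon),
                lexicon_tokens(location_lexicon), promo_terms)
  ok <- !(lemmatize(.vs_filler_vocab) %in% reserved) &
    !(.vs_filler_vocab %in% reserved)
  vocab <- .vs_filler_vocab[ok]
  assert_that(length(vocab) >= 20,
              "custom lexicons leave too little filler vocabulary")
  vocab
}

# n random posting times (integer seconds, so JSONL round-trips exactly).
random_times <- function(n) {
  span <- as.numeric(difftime(.vs_period_end, .vs_period_start, units = "secs"))
  .vs_period_start + floor(runif(n, 0, span))
}

# Pin each multi-post account's first/last post to the period endpoints so
# every such account has the same (low) posting rate.
pin_account_spans <- function(times, accounts) {
  for (idx in split(seq_along(accounts), accounts)) {
    if (length(idx) < 2) next
    times[idx[1]] <- .vs_period_start + floor(runif(1, 0, 86400))
    times[idx[length(idx)]] <- .vs_period_end - floor(runif(1, 0, 86400))
  }
  times
}

# Account sizes for a pool of n posts. Regular accounts get exactly `size`
# posts; a remainder spills into one or two strictly smaller accounts. The
# shape matters for the high-frequency rule: with pinned spans every regular
# account has the identical, maximal rate, so the maximum is always the
# majority value and sits below mean + k*SD -- no clean or low-rate
# contaminant account can be flagged as a heavy poster.
allocate_pinned_sizes <- function(n, size) {
  if (n == 0) return(integer(0))
  size <- max(2L, as.integer(size))
  m <- n %/% size
  r <- n %% size
  if (m == 0L) return(n)
  if (r == 0L) return(rep.int(size, m))
  if (r == 1L) {
    # avoid both a size+1 outlier and an unpinnable single-post account
    extra <- size + 1L
    return(c(rep.int(size, m - 1L), extra %/% 2L, extra - extra %/% 2L))
  }
  c(rep.int(size, m), r)
}

pooled_accounts <- function(n, prefix, per_account = 20) {
  if (n == 0) return(character(0))
  sizes <- allocate_pinned_sizes(n, per_account)
  rep(sprintf("%s%04d", prefix, seq_along(sizes)), sizes)
}

build_text <- function(filler_words, inserts) {
  slots <- sort(sample.int(length(filler_words) + 1, length(inserts),
                           replace = TRUE)) - 1L
  out <- character(0)
  prev <- 0L
  for (j in seq_along(inserts)) {
    out <- c(out, filler_words[seq_len(slots[j])[seq_len(slots[j]) > prev]],
             inserts[j])
    prev <- max(prev, slots[j])
  }
  if (prev < length(filler_words)) {
    out <- c(out, filler_words[(prev + 1):length(filler_words)])
  }
  paste(out, collapse = " ")
}

#' Generate a synthetic tweet corpus with ground truth
#'
#' Returns exactly `n_posts` records, each labeled with its contaminant kind
#' (or `"clean"` plus its planted category set and keywords). Every clean
#' post's text contains at least one vaping gate term and one keyword from
#' each planted category, embedded in filler drawn from a vocabulary
#' disjoint from both lexicons -- so a clean post's matched categories equal
#' exactly its planted categories. Duplicates are exact text copies of
#' sampled clean posts under distinct post ids and strictly later
#' timestamps. Identical specs yield byte-identical corpora.
#'
#' @param spec A [corpus_spec()].
#' @param vaping_terms,location_lexicon Lexicons the planted posts are built
#'   against; defaults are the bundled ones.
#' @return A corpus tibble (see [tweet_corpus()]) with `truth_labels` set on
#'   every record.
#' @export
generate_corpus <- function(spec,
                            vaping_terms = default_vaping_lexicon(),
                            location_lexicon = default_location_lexicon()) {
  assert_that(inherits(spec, "corpus_spec"), "spec must be a corpus_spec")
  set.seed(spec$seed)
  n <- spec$n_posts
  counts <- round(spec$fracs * n)
  over <- sum(counts) - n
  for (k in rev(seq_along(counts))) {   # trim lowest-priority kinds first
    if (over <= 0) break
    cut <- min(counts[k], over)
    counts[k] <- counts[k] - cut
    over <- over - cut
  }
  n_clean <- n - sum(counts)
  assert_that(counts[["duplicate"]] == 0 || n_clean > 0,
              "cannot plant duplicates without clean posts")

  mixture <- spec$category_mixture
  filler <- filler_vocabulary(vaping_terms, location_lexicon)
  vsurf <- validated_vaping_surfaces(vaping_terms)
  ksurf <- validated_surface_table(location_lexicon)
  vterms <- names(vsurf)

  rand_filler <- function() sample(filler, sample(5:12, 1), replace = TRUE)
  vaping_insert <- function() {
    s <- vsurf[[sample(vterms, 1)]]
    s[sample.int(length(s), 1)]
  }
  plain_text <- function() build_text(rand_filler(), vaping_insert())

  parts <- list()

  ## -- clean posts ---------------------------------------------------------
  if (n_clean > 0) {
    cats <- names(mixture)
    primary <- sample(cats, n_clean, replace = TRUE, prob = mixture)
    labels <- as.list(primary)
    if (length(cats) >= 2 && spec$multi_label_rate > 0) {
      dbl <- runif(n_clean) < spec$multi_label_rate
      for (i in which(dbl)) {
        rest <- setdiff(cats, primary[i])
        p <- mixture[rest] / sum(mixture[rest])
        labels[[i]] <- c(primary[i], sample(rest, 1, prob = p))
      }
    }
    make_one <- function(cat_set) {
      kws <- vapply(cat_set, function(cat) {
        kw <- sample(location_lexicon$entries[[cat]], 1)
        kw
      }, character(1))
      inserts <- c(vaping_insert(),
                   vapply(kws, function(kw) {
                     s <- ksurf[[kw]]
                     s[sample.int(length(s), 1)]
                   }, character(1)))
      list(text = build_text(rand_filler(), sample(inserts)),
           keywords = kws)
    }
    built <- lapply(labels, make_one)
    texts <- vapply(built, `[[`, character(1), "text")
    for (round in 1:25) {          # clean texts must be globally unique
      dup <- which(duplicated(texts))
      if (!length(dup)) break
      for (i in dup) {
        built[[i]] <- make_one(labels[[i]])
        texts[i] <- built[[i]]$text
      }
    }
    assert_that(!anyDuplicated(texts), "could not de-collide clean texts")
    acc_size <- if (is.null(spec$n_accounts)) 20L else {
      max(2L, n_clean %/% max(1L, as.integer(spec$n_accounts)))
    }
    sizes <- allocate_pinned_sizes(n_clean, acc_size)
    accounts <- rep(sprintf("user%05d", seq_along(sizes)), sizes)
    times <- pin_account_spans(random_times(n_clean), accounts)
    parts$clean <- tibble::tibble(
      account_id = accounts, text = texts, lang = "en",
      created_at = times, is_retweet = FALSE,
      truth_labels = lapply(seq_len(n_clean), function(i) {
        list(kind = "clean", categories = labels[[i]],
             keywords = as.list(built[[i]]$keywords))
      })
    )
  }

  ## -- retweets ------------------------------------------------------------
  if (counts[["retweet"]] > 0) {
    m <- counts[["retweet"]]
    texts <- sprintf("RT @%s: %s",
                     sprintf("someone%03d", sample.int(500, m, replace = TRUE)),
                     vapply(seq_len(m), function(i) plain_text(),
                            character(1)))
    accounts <- pooled_accounts(m, "rtuser")
    parts$retweet <- tibble::tibble(
      account_id = accounts, text = texts, lang = "en",
      created_at = pin_account_spans(random_times(m), accounts),
      is_retweet = TRUE,
      truth_labels = rep(list(list(kind = "retweet")), m)
    )
  }

  ## -- non-English posts ---------------------------------------------------
  if (counts[["non_english"]] > 0) {
    m <- counts[["non_english"]]
    langs <- sample(names(.vs_nonenglish_banks), m, replace = TRUE)
    texts <- vapply(langs, function(l) {
      paste(sample(.vs_nonenglish_banks[[l]], sample(4:9, 1),
                   replace = TRUE), collapse = " ")
    }, character(1), USE.NAMES = FALSE)
    accounts <- pooled_accounts(m, "intl")
    parts$non_english <- tibble::tibble(
      account_id = accounts, text = texts, lang = langs,
      created_at = pin_account_spans(random_times(m), accounts),
      is_retweet = FALSE,
      truth_labels = rep(list(list(kind = "non_english")), m)
    )
  }

  ## -- bot accounts (burst posting within one calendar day) ----------------
  if (counts[["bot"]] > 0) {
    m <- counts[["bot"]]
    k <- max(1L, m %/% as.integer(spec$bot_posts_per_day))
    sizes <- rep(m %/% k, k)
    if (m %% k > 0) sizes[seq_len(m %% k)] <- sizes[seq_len(m %% k)] + 1L
    accounts <- rep(sprintf("bot%04d", seq_len(k)), sizes)
    day0 <- sample(0:364, k, replace = TRUE)
    times <- .vs_period_start + rep(day0, sizes) * 86400 +
      floor(runif(m, 0, 86400))
    parts$bot <- tibble::tibble(
      account_id = accounts,
      text = vapply(seq_len(m), function(i) plain_text(), character(1)),
      lang = "en", created_at = times, is_retweet = FALSE,
      truth_labels = rep(list(list(kind = "bot")), m)
    )
  }

  ## -- high-frequency accounts (two-day bursts) ----------------------------
  if (counts[["high_freq"]] > 0) {
    m <- counts[["high_freq"]]
    per <- as.integer(2 * spec$high_freq_posts_per_day)
    k <- max(1L, m %/% per)
    sizes <- rep(m %/% k, k)
    if (m %% k > 0) sizes[seq_len(m %% k)] <- sizes[seq_len(m %% k)] + 1L
    accounts <- rep(sprintf("heavy%04d", seq_len(k)), sizes)
    day0 <- sample(0:363, k, replace = TRUE)
    times <- .vs_period_start + rep(day0, sizes) * 86400 +
      floor(runif(m, 0, 2 * 86400))
    parts$high_freq <- tibble::tibble(
      account_id = accounts,
      text = vapply(seq_len(m), function(i) plain_text(), character(1)),
      lang = "en", created_at = times, is_retweet = FALSE,
      truth_labels = rep(list(list(kind = "high_freq")), m)
    )
  }

  ## -- promotional posts ---------------------------------------------------
  if (counts[["promotional"]] > 0) {
    m <- counts[["promotional"]]
    texts <- vapply(seq_len(m), function(i) {
      paste(build_text(rand_filler(),
                       c(vaping_insert(), sample(.vs_promo_phrases, 1))),
            sprintf("https://deals.example/%06d",
                    sample.int(999999, 1)))
    }, character(1))
    accounts <- pooled_accounts(m, "promouser")
    parts$promotional <- tibble::tibble(
      account_id = accounts, text = texts, lang = "en",
      created_at = pin_account_spans(random_times(m), accounts),
      is_retweet = FALSE,
      truth_labels = rep(list(list(kind = "promotional")), m)
    )
  }

  ## -- assign ids, then plant duplicates of finalized clean posts ----------
  body <- dplyr::bind_rows(parts)
  body$post_id <- sprintf("t%08d", seq_len(nrow(body)))

  if (counts[["duplicate"]] > 0) {
    m <- counts[["duplicate"]]
    clean_rows <- which(vapply(body$truth_labels,
                               function(l) l$kind == "clean", TRUE))
    src <- sample(clean_rows, m, replace = TRUE)
    # copies sit a fixed hour after their source; accounts take sources
    # round-robin in time order, so every duplicate account spans most of
    # the period and its posting rate stays low
    src <- src[order(body$created_at[src], src)]
    k <- max(1L, m %/% 10L)
    accounts <- sprintf("dupuser%04d", rep_len(seq_len(k), m))
    dup <- tibble::tibble(
      account_id = accounts,
      text = body$text[src], lang = "en",
      created_at = body$created_at[src] + 3600,
      is_retweet = FALSE,
      truth_labels = lapply(src, function(s) {
        list(kind = "duplicate", source_post_id = body$post_id[s])
      }),
      post_id = sprintf("t%08d", nrow(body) + seq_len(m))
    )
    body <- dplyr::bind_rows(body, dup)
  }

  body <- body[sample.int(nrow(body)), , drop = FALSE]
  tweet_corpus(post_id = body$post_id, account_id = body$account_id,
               text = body$text, lang = body$lang,
               created_at = body$created_at, is_retweet = body$is_retweet,
               truth_labels = body$truth_labels)
}

#' Ground-truth category prevalence of a labeled corpus
#'
#' Computes the prevalence table of planted categories among clean posts,
#' from `truth_labels` only (never from text).
#'
#' @param records A corpus tibble in which every record carries
#'   `truth_labels`.
#' @return A `prevalence_table` (see [compute_prevalence()]); empty with
#'   `n_total = 0` when there are no clean posts.
#' @export
mixture_truth <- function(records) {
  missing <- vapply(records$truth_labels, is.null, TRUE)
  assert_that(!any(missing), "record(s) missing truth_labels: ",
              paste(head(records$post_id[missing], 3), collapse = ", "))
  kinds <- vapply(records$truth_labels, function(l) l$kind, character(1))
  clean <- which(kinds == "clean")
  cats <- unlist(lapply(records$truth_labels[clean],
                        function(l) l$categories))
  counts <- table(factor(cats, levels = unique(cats)))
  new_prevalence_table(
    counts = setNames(as.integer(counts), names(counts)),
    n_total = length(clean),
    n_users = length(unique(records$account_id[clean]))
  )
}
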