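# Independent brute-force oracle for the keyword matcher: for every keyword,
# scan every token position explicitly. Shares only the normalization layer
# with the production matcher (keyword matching is defined on lemma tokens);
# the matching logic itself is a plain positional scan, no indexing.

oracle_fires <- function(toks, kw_tokens) {
  L <- length(kw_tokens)
  n <- length(toks)
  if (n < L) return(FALSE)
  if (L == 1) return(any(toks == kw_tokens))  # vectorized positional scan
  for (s in seq_len(n - L + 1)) {
    if (all(toks[s:(s + L - 1)] == kw_tokens)) return(TRUE)
  }
  FALSE
}

# Canonical form shared by production and oracle outputs, so equality is a
# single expectation per corpus.
canonical_prod <- function(cl) {
  out <- lapply(seq_len(nrow(cl)), function(i) {
    mk <- cl$matched_keywords[[i]]
    list(categories = sort(cl$categories[[i]]),
         matched = lapply(mk[sort(names(mk))], sort))
  })
  names(out) <- cl$post_id
  out[order(names(out))]
}

canonical_oracle <- function(oc) {
  out <- lapply(oc, function(x) {
    mk <- x$matched_keywords
    list(categories = sort(x$categories),
         matched = lapply(mk[sort(names(mk))], sort))
  })
  names(out) <- vapply(oc, `[[`, character(1), "post_id")
  out[order(names(out))]
}

# Lemmatize every keyword's tokens once per lexicon; the per-post matching
# below stays a plain scan over every keyword and token position.
oracle_compile <- function(lexicon) {
  lapply(lexicon$entries, function(kws) {
    setNames(lapply(kws, function(kw) {
      lemmatize(strsplit(kw, " ", fixed = TRUE)[[1]])
    }), kws)
  })
}

oracle_match <- function(toks, compiled) {
  matched <- list()
  for (cat in names(compiled)) {
    fired <- character(0)
    for (kw in names(compiled[[cat]])) {
      if (oracle_fires(toks, compiled[[cat]][[kw]])) fired <- c(fired, kw)
    }
    if (length(fired)) matched[[cat]] <- fired
  }
  matched
}

oracle_classify <- function(records, vaping = default_vaping_lexicon(),
                            location = default_location_lexicon()) {
  norm <- normalize_corpus(records)
  cvap <- oracle_compile(vaping)
  cloc <- oracle_compile(location)
  out <- list()
  for (i in seq_len(nrow(norm))) {
    toks <- norm$tokens[[i]]
    if (length(oracle_match(toks, cvap)) == 0) next
    mk <- oracle_match(toks, cloc)
    if (length(mk) == 0) next
    out[[length(out) + 1]] <- list(post_id = norm$post_id[i],
                                   categories = names(mk),
                                   matched_keywords = mk)
  }
  out
}

truth_kinds <- function(records) {
  vapply(records$truth_labels, function(l) l$kind, character(1))
}

truth_categories <- function(records) {
  lapply(records$truth_labels, function(l) l$categories)
}

# A tiny hand-built corpus for filter unit tests.
mini_corpus <- function(texts, account_id = "acct1",
                        lang = "en", is_retweet = FALSE,
                        created_at = NULL) {
  n <- length(texts)
  tweet_corpus(
    post_id = sprintf("p%03d", seq_len(n)),
    account_id = account_id, text = texts, lang = lang,
    created_at = created_at %||%
      (as.POSIXct("2018-06-01", tz = "UTC") + 3600 * seq_len(n)),
    is_retweet = is_retweet
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
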