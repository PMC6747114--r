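# Text normalization: NFKC -> strip URLs/hashtags/mentions/punctuation ->
# lowercase -> tokenize -> lemmatize. Deterministic by construction: the
# lemmatizer is an exception table plus suffix rules, no model downloads.

.vs_url_re     <- "(?i)\\b(?:https?://|www\\.)\\S+|\\bt\\.co/\\S+"
.vs_hashtag_re <- "#[\\p{L}\\p{N}_]+"
.vs_mention_re <- "@[A-Za-z0-9_]+"
.vs_nonword_re <- "[^\\p{L}\\p{N}]+"

#' Strip stream artifacts from raw text
#'
#' Removes URLs (http/https, www, t.co shortlinks), hashtags (by default the
#' whole token, marker plus word), and @-mentions; replaces punctuation and
#' all other non-alphanumeric symbols (including emoji) with spaces; NFKC
#' unicode-normalizes first and collapses repeated whitespace. Case is
#' preserved; lowercasing happens in [normalize_post()].
#'
#' @param text Character vector.
#' @param keep_hashtag_words Keep the hashtag's word (dropping only the
#'   `#`)? Default `FALSE`: the entire hashtag token is removed.
#' @return Character vector of cleaned text.
#' @export
#' @examples
#' strip_artifacts("Vaping at the #party http://t.co/ab!")
strip_artifacts <- function(text, keep_hashtag_words = FALSE) {
  x <- stringi::stri_trans_nfkc(as.character(text))
  x <- stringi::stri_replace_all_regex(x, .vs_url_re, " ")
  if (keep_hashtag_words) {
    x <- stringi::stri_replace_all_fixed(x, "#", " ")
  } else {
    x <- stringi::stri_replace_all_regex(x, .vs_hashtag_re, " ")
  }
  x <- stringi::stri_replace_all_regex(x, .vs_mention_re, " ")
  x <- stringi::stri_replace_all_regex(x, .vs_nonword_re, " ")
  stringi::stri_trim_both(stringi::stri_replace_all_regex(x, "\\s+", " "))
}

.vs_lemma_env <- new.env(parent = emptyenv())

default_lemma_exceptions <- function() {
  if (is.null(.vs_lemma_env$exceptions)) {
    path <- system.file("extdata", "lemma_exceptions.tsv",
                        package = "vapescope", mustWork = TRUE)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             fileEncoding = "UTF-8")
    .vs_lemma_env$exceptions <- setNames(tab$lemma, tab$surface)
  }
  .vs_lemma_env$exceptions
}

lemmatize_one <- function(tok, exceptions) {
  hit <- exceptions[[tok]]
  if (!is.null(hit)) return(hit)
  n <- nchar(tok)
  # regular plurals
  if (n >= 5 && endsWith(tok, "ies")) {
    return(paste0(substr(tok, 1, n - 3), "y"))
  }
  if (n >= 5 && grepl("(ss|x|ch|sh|z)es$", tok)) {
    return(substr(tok, 1, n - 2))
  }
  if (n >= 4 && endsWith(tok, "s") &&
      !grepl("(ss|us|is)$", tok)) {
    return(substr(tok, 1, n - 1))
  }
  # progressive / past verb forms with final-consonant dedoubling
  dedouble <- function(stem) {
    m <- nchar(stem)
    if (m >= 3 && substr(stem, m, m) == substr(stem, m - 1, m - 1) &&
        !grepl("(ss|ll|zz)$", stem)) {
      substr(stem, 1, m - 1)
    } else stem
  }
  if (n >= 6 && endsWith(tok, "ing")) {
    return(dedouble(substr(tok, 1, n - 3)))
  }
  if (n >= 5 && endsWith(tok, "ed")) {
    return(dedouble(substr(tok, 1, n - 2)))
  }
  tok
}

#' Lemmatize lowercase tokens
#'
#' Rule-based lemmatizer: an exception table (bundled, user-extensible TSV)
#' consulted first, then regular-plural rules (`parties` to `party`,
#' `churches` to `church`, `cars` to `car`) and inflected-verb rules with
#' final-consonant dedoubling (`shopping` to `shop`, `worked` to `work`).
#' Irregular forms relevant to the bundled lexicons (`vaping` to `vape`,
#' `drove` to `drive`) live in the exception table.
#'
#' @param tokens Character vector of lowercase tokens.
#' @param exceptions Named character vector mapping surface forms to lemmas;
#'   defaults to the bundled table.
#' @return Character vector of lemmas, same length as `tokens`.
#' @export
#' @examples
#' lemmatize(c("vaping", "cars", "parties", "driving"))
lemmatize <- function(tokens, exceptions = default_lemma_exceptions()) {
  if (!length(tokens)) return(character(0))
  uniq <- unique(tokens)
  exc <- as.list(exceptions)
  lem <- vapply(uniq, function(tok) {
    # iterate to a fixpoint so stacked suffixes ("crossings") reduce fully;
    # this makes the whole normalization pipeline idempotent
    for (i in 1:5) {
      nxt <- lemmatize_one(tok, exc)
      if (identical(nxt, tok)) break
      tok <- nxt
    }
    tok
  }, character(1), USE.NAMES = FALSE)
  lem[match(tokens, uniq)]
}

# Vectorized core: raw texts -> list of lemma-token vectors.
normalize_text <- function(text, keep_hashtag_words = FALSE) {
  cleaned <- strip_artifacts(text, keep_hashtag_words = keep_hashtag_words)
  lowered <- stringi::stri_trans_tolower(cleaned)
  toks <- stringi::stri_split_regex(lowered, "\\s+", omit_empty = TRUE)
  flat <- unlist(toks, use.names = FALSE)
  if (!length(flat)) return(lapply(toks, function(t) character(0)))
  lems <- lemmatize(flat)
  lens <- lengths(toks)
  split_idx <- rep.int(seq_along(toks), lens)
  out <- vector("list", length(toks))
  out[lens > 0] <- split(lems, split_idx)
  out[lens == 0] <- list(character(0))
  out
}

#' Normalize a single post
#'
#' Full normalization pipeline: [strip_artifacts()], lowercase, whitespace
#' tokenization, [lemmatize()]. Empty tokens are dropped; token order follows
#' the surface order of the source words.
#'
#' @param record A one-row corpus tibble (or a list with `post_id` and
#'   `text`), or a plain character scalar.
#' @param keep_hashtag_words Passed to [strip_artifacts()].
#' @return A list of class `normalized_post` with `post_id`, `tokens`,
#'   and `raw_text`.
#' @export
#' @examples
#' normalize_post("Vaping in cars and trains")
normalize_post <- function(record, keep_hashtag_words = FALSE) {
  if (is.character(record)) {
    record <- list(post_id = NA_character_, text = record)
  }
  tokens <- normalize_text(record$text[[1]],
                           keep_hashtag_words = keep_hashtag_words)[[1]]
  structure(list(post_id = record$post_id[[1]],
                 tokens = tokens,
                 raw_text = record$text[[1]]),
            class = "normalized_post")
}

#' Normalize every post in a corpus
#'
#' @param records A corpus tibble.
#' @inheritParams normalize_post
#' @return A tibble with `post_id`, `tokens` (list-column of lemma vectors)
#'   and `raw_text`.
#' @export
normalize_corpus <- function(records, keep_hashtag_words = FALSE) {
  tibble::tibble(
    post_id = records$post_id,
    tokens = normalize_text(records$text,
                            keep_hashtag_words = keep_hashtag_words),
    raw_text = records$text
  )
}
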