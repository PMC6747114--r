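# Rule-based multi-label classification. A single-word keyword fires iff it
# equals some lemma token exactly; a multi-word phrase fires iff its
# lemmatized token sequence occurs contiguously. Whole-token matching is
# deliberate: substring matching would make "car" fire on "care".

# Compile a lexicon for matching: lemmatize each keyword's tokens once and
# store the space-joined key alongside the original keyword and category.
compile_lexicon <- function(lex) {
  cats <- names(lex$entries)
  rows <- lapply(cats, function(cat) {
    kws <- lex$entries[[cat]]
    keys <- vapply(kws, function(kw) {
      paste(lemmatize(strsplit(kw, " ", fixed = TRUE)[[1]]), collapse = " ")
    }, character(1), USE.NAMES = FALSE)
    data.frame(category = cat, keyword = kws, key = keys,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$category <- factor(out$category, levels = cats)
  out
}

# Padded space-joined token string; a whole-token (or contiguous-phrase)
# match is then a fixed-string search for " key ".
join_tokens <- function(tokens) {
  vapply(tokens, function(t) paste0(" ", paste(t, collapse = " "), " "),
         character(1))
}

# Logical matrix posts x keywords.
match_matrix <- function(joined, compiled) {
  if (length(joined) == 0) return(matrix(FALSE, 0, nrow(compiled)))
  m <- vapply(paste0(" ", compiled$key, " "), function(pat) {
    stringi::stri_detect_fixed(joined, pat)
  }, logical(length(joined)), USE.NAMES = FALSE)
  if (!is.matrix(m)) m <- matrix(m, nrow = length(joined))
  m
}

classified_from_hits <- function(post_id, hits, compiled) {
  fired <- compiled[hits, , drop = FALSE]
  cats <- levels(compiled$category)[sort(unique(as.integer(fired$category)))]
  mk <- lapply(cats, function(cat) {
    unique(fired$keyword[as.character(fired$category) == cat])
  })
  names(mk) <- cats
  structure(list(post_id = post_id, categories = cats,
                 matched_keywords = mk),
            class = "classified_post")
}

#' Match lexicon keywords against a normalized post
#'
#' @param post A `normalized_post` (see [normalize_post()]) or a character
#'   vector of lemma tokens.
#' @param lexicon A [lexicon()] object.
#' @return A `classified_post`: list with `post_id`, `categories` (character
#'   vector, possibly empty, in lexicon order), and `matched_keywords`
#'   (named list mapping each matched category to the keywords that fired).
#' @export
#' @examples
#' p <- normalize_post("vape in my bedroom")
#' match_keywords(p, default_location_lexicon())
match_keywords <- function(post, lexicon) {
  if (is.character(post)) {
    post <- structure(list(post_id = NA_character_, tokens = post),
                      class = "normalized_post")
  }
  compiled <- compile_lexicon(lexicon)
  joined <- join_tokens(list(post$tokens))
  hits <- as.vector(match_matrix(joined, compiled))
  classified_from_hits(post$post_id, hits, compiled)
}

#' Classify a filtered corpus into location categories
#'
#' Normalizes each record, keeps only records containing at least one vaping
#' gate term (whole-token, post-lemmatization), classifies the kept records
#' against the location lexicon, and drops records with zero location
#' matches. The survivors are the analytic sample.
#'
#' @param records A corpus tibble (already passed through the filter
#'   cascade).
#' @param vaping_terms Gate lexicon; default [default_vaping_lexicon()].
#' @param location_lexicon Location lexicon; default
#'   [default_location_lexicon()].
#' @param mode `"multi_label"` (a post counts in every category whose
#'   keywords it contains) or `"first_match"` (only the first matching
#'   category in lexicon order).
#' @param keep_hashtag_words Passed to normalization.
#' @return A tibble with `post_id`, `account_id`, `categories` (list-column)
#'   and `matched_keywords` (list-column of named lists), one row per
#'   analytic-sample post, in input order.
#' @export
classify_corpus <- function(records,
                            vaping_terms = default_vaping_lexicon(),
                            location_lexicon = default_location_lexicon(),
                            mode = c("multi_label", "first_match"),
                            keep_hashtag_words = FALSE) {
  mode <- match.arg(mode)
  assert_that(length(vaping_terms$entries) > 0 &&
                length(location_lexicon$entries) > 0, "empty lexicon")
  tokens <- normalize_text(records$text,
                           keep_hashtag_words = keep_hashtag_words)
  joined <- join_tokens(tokens)

  gate <- compile_lexicon(vaping_terms)
  gated <- rowSums(match_matrix(joined, gate)) > 0

  compiled <- compile_lexicon(location_lexicon)
  hitmat <- match_matrix(joined[gated], compiled)
  idx <- which(gated)
  classified <- lapply(seq_along(idx), function(j) {
    cp <- classified_from_hits(records$post_id[idx[j]], hitmat[j, ], compiled)
    if (mode == "first_match" && length(cp$categories) > 1) {
      first <- cp$categories[[1]]
      cp$categories <- first
      cp$matched_keywords <- cp$matched_keywords[first]
    }
    cp
  })
  keep <- vapply(classified, function(cp) length(cp$categories) > 0, TRUE)
  classified <- classified[keep]
  tibble::tibble(
    post_id = vapply(classified, `[[`, character(1), "post_id"),
    account_id = records$account_id[idx[keep]],
    categories = lapply(classified, `[[`, "categories"),
    matched_keywords = lapply(classified, `[[`, "matched_keywords")
  )
}

#' Write classified posts as JSONL or long-format CSV
#'
#' @param classified Output of [classify_corpus()].
#' @param path Destination file.
#' @param format `"jsonl"` (post_id, categories, matched_keywords per line)
#'   or `"csv"` (long format: post_id, category, keyword).
#' @return `path`, invisibly.
#' @export
write_classified <- function(classified, path,
                             format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(classified)), function(i) {
      as.character(jsonlite::toJSON(list(
        post_id = classified$post_id[i],
        categories = classified$categories[[i]],
        matched_keywords = classified$matched_keywords[[i]]
      ), auto_unbox = FALSE, digits = NA))
    }, character(1))
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(enc2utf8(lines), con, useBytes = TRUE)
  } else {
    rows <- do.call(rbind, lapply(seq_len(nrow(classified)), function(i) {
      mk <- classified$matched_keywords[[i]]
      do.call(rbind, lapply(names(mk), function(cat) {
        data.frame(post_id = classified$post_id[i], category = cat,
                   keyword = mk[[cat]], stringsAsFactors = FALSE)
      }))
    }))
    write.csv(rows, path, row.names = FALSE)
  }
  invisible(path)
}
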