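#' Build a tweet corpus tibble
#'
#' A corpus is a tibble with one row per post and columns `post_id`,
#' `account_id`, `text`, `lang` (BCP-47-style tag, `"und"` when unknown),
#' `created_at` (POSIXct, UTC), `is_retweet`, plus two list-columns:
#' `truth_labels` (ground-truth annotations on synthetic corpora, `NULL`
#' on real data) and `extra` (unrecognized JSON fields, preserved opaquely
#' on round-trip).
#'
#' @param post_id,account_id,text Character vectors (recycled to the same
#'   length where scalar).
#' @param lang Language tags; default `"en"`.
#' @param created_at POSIXct timestamps (UTC).
#' @param is_retweet Logical; when `NA`, inferred from a leading `"RT @"`.
#' @param truth_labels Optional list of per-post annotation lists.
#' @param extra Optional list of per-post named lists of extra fields.
#' @return A `tbl_df` corpus.
#' @export
tweet_corpus <- function(post_id, account_id, text, lang = "en",
                         created_at = .vs_period_start, is_retweet = NA,
                         truth_labels = NULL, extra = NULL) {
  n <- length(post_id)
  assert_that(!anyDuplicated(post_id), "post_id values must be unique")
  assert_that(!anyNA(text), "text may be empty but never absent")
  is_retweet <- rep_len(is_retweet, n)
  text <- as.character(text)
  infer <- is.na(is_retweet)
  is_retweet[infer] <- startsWith(text[infer], "RT @")
  tibble::tibble(
    post_id = as.character(post_id),
    account_id = rep_len(as.character(account_id), n),
    text = text,
    lang = rep_len(as.character(lang), n),
    created_at = rep_len(as.POSIXct(created_at, tz = "UTC"), n),
    is_retweet = as.logical(is_retweet),
    truth_labels = truth_labels %||% rep(list(NULL), n),
    extra = extra %||% rep(list(NULL), n)
  )
}

.vs_required_fields <- c("post_id", "account_id", "text")
.vs_known_fields <- c(.vs_required_fields,
                      "lang", "created_at", "is_retweet", "truth_labels")

parse_record_json <- function(line) {
  rec <- tryCatch(jsonlite::fromJSON(line, simplifyVector = TRUE,
                                     simplifyDataFrame = FALSE,
                                     simplifyMatrix = FALSE),
                  error = function(e) NULL)
  if (is.null(rec) || !is.list(rec)) return(NULL)
  if (!all(.vs_required_fields %in% names(rec))) return(NULL)
  rec
}

#' Read a JSON-lines corpus
#'
#' One JSON object per line with keys `post_id`, `account_id`, `text`, and
#' optionally `lang`, `created_at` (ISO-8601), `is_retweet`, `truth_labels`;
#' any other keys are kept in the `extra` list-column and written back by
#' [write_corpus()].
#'
#' @param path Path to a JSONL file.
#' @param strict When `TRUE`, a malformed line (bad JSON or a missing
#'   required field) is an error; otherwise it is skipped and counted in the
#'   `n_skipped` attribute of the result.
#' @return A corpus tibble, in file order, with attribute `n_skipped`.
#' @export
read_corpus <- function(path, strict = FALSE) {
  assert_that(file.exists(path), "corpus file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, parse_record_json)
  bad <- vapply(recs, is.null, TRUE)
  if (any(bad) && strict) {
    vs_stop("malformed corpus line(s): ",
            paste(head(which(bad), 5), collapse = ", "),
            class = "vapescope_parse_error")
  }
  recs <- recs[!bad]
  n <- length(recs)
  get_chr <- function(field, default = NA_character_) {
    vapply(recs, function(r) {
      v <- r[[field]]
      if (is.null(v)) default else as.character(v)
    }, character(1))
  }
  get_lgl <- function(field) {
    vapply(recs, function(r) {
      v <- r[[field]]
      if (is.null(v)) NA else as.logical(v)
    }, logical(1))
  }
  labels <- lapply(recs, function(r) r[["truth_labels"]])
  extra <- lapply(recs, function(r) {
    e <- r[setdiff(names(r), .vs_known_fields)]
    if (length(e)) e else NULL
  })
  out <- tweet_corpus(
    post_id = get_chr("post_id"),
    account_id = get_chr("account_id"),
    text = get_chr("text", default = ""),
    lang = { l <- get_chr("lang"); l[is.na(l)] <- "und"; l },
    created_at = parse_iso8601(get_chr("created_at")),
    is_retweet = if (n) get_lgl("is_retweet") else logical(0),
    truth_labels = labels,
    extra = extra
  )
  attr(out, "n_skipped") <- sum(bad)
  out
}

#' Write a corpus as JSON lines
#'
#' Inverse of [read_corpus()]: one JSON object per line, UTF-8,
#' ISO-8601 timestamps. `truth_labels` is emitted only when present and
#' `extra` fields are merged back at the top level.
#'
#' @param records A corpus tibble.
#' @param path Destination path.
#' @return Number of records written, invisibly.
#' @export
write_corpus <- function(records, path) {
  n <- nrow(records)
  ts <- ifelse(is.na(records$created_at), NA_character_,
               format_iso8601(records$created_at))
  lines <- vapply(seq_len(n), function(i) {
    obj <- list(
      post_id = records$post_id[i],
      account_id = records$account_id[i],
      text = records$text[i],
      lang = records$lang[i],
      created_at = ts[i],
      is_retweet = records$is_retweet[i]
    )
    if (!is.null(records$truth_labels[[i]])) {
      obj$truth_labels <- records$truth_labels[[i]]
    }
    ex <- records$extra[[i]]
    if (!is.null(ex)) obj[names(ex)] <- ex
    as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null",
                                  digits = NA, POSIXt = "ISO8601"))
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (n > 0) writeLines(enc2utf8(lines), con, useBytes = TRUE)
  invisible(n)
}
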