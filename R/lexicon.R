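#' Construct a keyword lexicon
#'
#' A lexicon maps category names to sets of lowercase keywords or phrases.
#' Keywords are trimmed, lowercased and deduplicated; category order is
#' preserved as given and is meaningful (it is the tie-break order for
#' first-match classification and the row order of reports).
#'
#' @param entries Named list; each element a character vector of keywords.
#' @param name Lexicon name (a short label used in logs and reports).
#' @param version Free-form version string.
#' @return An object of class `vape_lexicon`.
#' @export
#' @examples
#' lexicon(list(Stores = c("shop", "store")), name = "mini")
lexicon <- function(entries, name = "lexicon", version = "1") {
  assert_that(is.list(entries) && length(entries) > 0,
              "lexicon entries must be a nonempty named list")
  cats <- names(entries)
  assert_that(!is.null(cats) && all(nzchar(cats)),
              "every lexicon category needs a name")
  assert_that(!anyDuplicated(cats), "duplicate category name in lexicon")
  entries <- lapply(entries, function(kw) {
    kw <- trimws(tolower(as.character(kw)))
    kw <- unique(kw[nzchar(kw)])
    kw
  })
  bad <- vapply(entries, length, 1L) == 0L
  assert_that(!any(bad), "lexicon category with no keywords: ",
              paste(cats[bad], collapse = ", "))
  structure(list(name = name, entries = entries, version = version),
            class = "vape_lexicon")
}

#' @export
print.vape_lexicon <- function(x, ...) {
  cat(sprintf("<vape_lexicon '%s' v%s: %d categories, %d keywords>\n",
              x$name, x$version, length(x$entries),
              sum(lengths(x$entries))))
  invisible(x)
}

#' Read a lexicon from its plain-text format
#'
#' The format is line-oriented UTF-8: `[Category Name]` opens a category,
#' each subsequent non-blank line is one keyword or phrase, and `#` starts a
#' comment. Optional header comments `# name: ...` and `# version: ...` set
#' the metadata fields.
#'
#' @param path Path to a lexicon file.
#' @return A [lexicon()] object.
#' @export
load_lexicon <- function(path) {
  assert_that(file.exists(path), "lexicon file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  name <- sub("\\.[^.]*$", "", basename(path))
  version <- "1"
  entries <- list()
  current <- NULL
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (grepl("^#", line)) {
      m <- regmatches(line, regexec("^#\\s*(name|version)\\s*:\\s*(.+)$", line))[[1]]
      if (length(m) == 3) {
        if (m[2] == "name") name <- trimws(m[3]) else version <- trimws(m[3])
      }
      next
    }
    if (!nzchar(line)) next
    if (grepl("^\\[.+\\]$", line)) {
      current <- trimws(sub("^\\[(.+)\\]$", "\\1", line))
      assert_that(!current %in% names(entries),
                  "duplicate category name at line ", i, ": ", current)
      entries[[current]] <- character()
    } else {
      assert_that(!is.null(current),
                  "keyword before any [Category] header at line ", i)
      entries[[current]] <- c(entries[[current]], line)
    }
  }
  lexicon(entries, name = name, version = version)
}

#' Write a lexicon in the plain-text format read by [load_lexicon()]
#'
#' @param lex A [lexicon()] object.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  assert_that(inherits(lex, "vape_lexicon"), "not a vape_lexicon")
  lines <- c(sprintf("# name: %s", lex$name),
             sprintf("# version: %s", lex$version))
  for (cat in names(lex$entries)) {
    lines <- c(lines, "", sprintf("[%s]", cat), lex$entries[[cat]])
  }
  writeLines(enc2utf8(lines), path, useBytes = TRUE)
  invisible(path)
}

#' Bundled location-category lexicon
#'
#' Eleven location categories (social venues, living spaces, stores, modes of
#' transportation, schools, workplaces, healthcare offices, eateries,
#' correctional facilities, religious institutions, miscellaneous) with
#' field-standard keywords. Keywords are stored in lemma form; matching is
#' whole-token against lemmatized text.
#'
#' @return A [lexicon()] object with 11 categories.
#' @export
default_location_lexicon <- function() {
  load_lexicon(system.file("extdata", "location_categories.lex",
                           package = "vapescope", mustWork = TRUE))
}

#' Bundled vaping-term lexicon (gate terms)
#'
#' Twenty-six vaping-related terms used to gate posts into the analytic
#' sample. The bundled list is a reconstruction assembled from terms standard
#' in tobacco-control surveillance; it is fully overridable via
#' [load_lexicon()].
#'
#' @return A [lexicon()] object with a single category of 26 terms.
#' @export
default_vaping_lexicon <- function() {
  load_lexicon(system.file("extdata", "vaping_terms.lex",
                           package = "vapescope", mustWork = TRUE))
}

# All distinct tokens appearing in a lexicon's keywords (lemma space).
lexicon_tokens <- function(lex) {
  unique(unlist(strsplit(unlist(lex$entries, use.names = FALSE), " ",
                         fixed = TRUE)))
}
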