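# Prevalence of each location category over the analytic sample, with
# Wilson 95% intervals. The denominator is posts (not users, not keyword
# firings); under multi-label assignment the category counts may sum above
# the sample size, so percentages may sum above 100.

#' Wilson score interval for a binomial proportion
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return A two-column matrix (`low`, `high`) of proportions in `[0, 1]`.
#' @export
wilson_interval <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  cbind(low = pmax(0, centre - half), high = pmin(1, centre + half))
}

# Shared constructor: sorts rows descending by percent with Miscellaneous
# last (reporting convention), attaches Wilson intervals.
new_prevalence_table <- function(counts, n_total, n_users,
                                 top_keywords = NULL) {
  if (length(counts) == 0 || n_total == 0) {
    rows <- tibble::tibble(category = character(0), n_posts = integer(0),
                           percent = numeric(0), ci_low = numeric(0),
                           ci_high = numeric(0), top_keywords = character(0))
    return(structure(list(rows = rows, n_total = as.integer(n_total),
                          n_users = as.integer(n_users)),
                     class = "prevalence_table"))
  }
  ci <- wilson_interval(unname(counts), n_total)
  rows <- tibble::tibble(
    category = names(counts),
    n_posts = as.integer(counts),
    percent = 100 * as.numeric(counts) / n_total,
    ci_low = 100 * ci[, "low"],
    ci_high = 100 * ci[, "high"],
    top_keywords = if (is.null(top_keywords)) NA_character_ else
      unname(top_keywords[names(counts)])
  )
  misc <- rows$category == "Miscellaneous"
  ord <- order(-rows$percent, rows$category)
  ord <- c(ord[!misc[ord]], ord[misc[ord]])
  rows <- rows[ord, , drop = FALSE]
  structure(list(rows = rows, n_total = as.integer(n_total),
                 n_users = as.integer(n_users)),
            class = "prevalence_table")
}

#' Category prevalence over the analytic sample
#'
#' Counts, per category, the posts assigned to it; percentages use the
#' analytic sample size as denominator and carry Wilson 95% intervals
#' (the intervals are an addition of this implementation, marked as such in
#' rendered reports). Rows are sorted descending by percent with
#' Miscellaneous listed last.
#'
#' @param classified Output of [classify_corpus()]; must be nonempty and
#'   every post must carry at least one category.
#' @param account_map Optional named character vector mapping `post_id` to
#'   `account_id`, used to count distinct users; defaults to the
#'   `account_id` column of `classified` when present.
#' @param categories Optional character vector fixing the category universe
#'   (zero-count categories are then included).
#' @return A `prevalence_table`: list with `rows` (tibble: category,
#'   n_posts, percent, ci_low, ci_high, top_keywords), `n_total`, `n_users`.
#' @export
compute_prevalence <- function(classified, account_map = NULL,
                               categories = NULL) {
  assert_that(nrow(classified) > 0, "no classified posts")
  n_cats <- lengths(classified$categories)
  assert_that(all(n_cats >= 1), "classified post without a category")
  n_total <- nrow(classified)
  accounts <- if (!is.null(account_map)) {
    unname(account_map[classified$post_id])
  } else if ("account_id" %in% names(classified)) {
    classified$account_id
  } else {
    classified$post_id
  }
  cats <- unlist(classified$categories)
  universe <- categories %||% unique(cats)
  counts <- table(factor(cats, levels = universe))
  counts <- setNames(as.integer(counts), universe)

  kw_fired <- unlist(lapply(classified$matched_keywords, function(mk) {
    unlist(lapply(names(mk), function(cat) {
      paste0(cat, "\r", mk[[cat]])
    }))
  }))
  top_keywords <- setNames(rep(NA_character_, length(universe)), universe)
  if (length(kw_fired)) {
    tab <- sort(table(kw_fired), decreasing = TRUE)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    df <- data.frame(category = vapply(parts, `[[`, "", 1),
                     keyword = vapply(parts, `[[`, "", 2),
                     n = as.integer(tab), stringsAsFactors = FALSE)
    for (cat in universe) {
      kws <- df$keyword[df$category == cat]
      if (length(kws)) {
        top_keywords[[cat]] <- paste(head(kws, 3), collapse = ", ")
      }
    }
  }
  new_prevalence_table(counts, n_total,
                       n_users = length(unique(accounts)),
                       top_keywords = top_keywords)
}

#' @export
print.prevalence_table <- function(x, ...) {
  cat(sprintf("Analytic sample: %d posts from %d users\n",
              x$n_total, x$n_users))
  print(x$rows, n = nrow(x$rows))
  invisible(x)
}

# Round-half-even to 1 decimal, rendered as a fixed-point string.
format_percent <- function(p, digits = 1) {
  formatC(round(p, digits), format = "f", digits = digits)
}

#' Render a prevalence table
#'
#' Emits the table in the conventional layout (No., Locations, Illustrative
#' Keywords, %) with percentages rounded to one decimal (round-half-even).
#' Wilson intervals are included in the CSV and JSON forms, flagged by
#' column name as an addition to the conventional layout. The JSON form
#' round-trips through [prevalence_from_json()].
#'
#' @param table A `prevalence_table`.
#' @param format `"markdown"`, `"csv"`, or `"json"`.
#' @return A character scalar (the document).
#' @export
render_report <- function(table, format = c("markdown", "csv", "json")) {
  format <- match.arg(format)
  rows <- table$rows
  kw <- ifelse(is.na(rows$top_keywords), "", rows$top_keywords)
  if (format == "markdown") {
    lines <- c(
      sprintf("Analytic sample: %d posts from %d users", table$n_total,
              table$n_users),
      "",
      "| No. | Locations | Illustrative Keywords | % |",
      "|----:|-----------|-----------------------|---:|",
      sprintf("| %d. | %s | %s | %s |", seq_len(nrow(rows)), rows$category,
              kw, format_percent(rows$percent))
    )
    return(paste(lines, collapse = "\n"))
  }
  if (format == "csv") {
    df <- data.frame(
      no = seq_len(nrow(rows)), locations = rows$category,
      illustrative_keywords = kw, n_posts = rows$n_posts,
      percent = format_percent(rows$percent),
      wilson_ci_low = format_percent(rows$ci_low),
      wilson_ci_high = format_percent(rows$ci_high),
      stringsAsFactors = FALSE
    )
    con <- textConnection("out", "w", local = TRUE)
    write.csv(df, con, row.names = FALSE)
    close(con)
    return(paste(out, collapse = "\n"))
  }
  as.character(jsonlite::toJSON(list(
    n_total = table$n_total, n_users = table$n_users,
    rows = lapply(seq_len(nrow(rows)), function(i) list(
      no = i, category = rows$category[i],
      illustrative_keywords = kw[i],
      n_posts = rows$n_posts[i], percent = rows$percent[i],
      wilson_ci_low = rows$ci_low[i], wilson_ci_high = rows$ci_high[i]
    ))
  ), auto_unbox = TRUE, digits = NA, pretty = TRUE))
}

#' Reconstruct a prevalence table from its JSON rendering
#'
#' @param json Character scalar produced by
#'   `render_report(table, format = "json")`.
#' @return A `prevalence_table`.
#' @export
prevalence_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyDataFrame = TRUE)
  rows <- obj$rows
  if (NROW(rows) == 0) {
    return(new_prevalence_table(integer(0), obj$n_total, obj$n_users))
  }
  counts <- setNames(as.integer(rows$n_posts), rows$category)
  tk <- setNames(ifelse(nzchar(rows$illustrative_keywords),
                        rows$illustrative_keywords, NA_character_),
                 rows$category)
  new_prevalence_table(counts, n_total = obj$n_total,
                       n_users = obj$n_users, top_keywords = tk)
}
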