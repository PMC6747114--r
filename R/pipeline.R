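# End-to-end orchestration: read -> filter cascade -> vaping gate ->
# classify -> prevalence, with every intermediate written to the output
# directory. Deterministic given the configuration: outputs carry no wall
# clock, so a rerun is byte-identical.

#' Pipeline configuration
#'
#' @param input Path to a JSONL corpus (optional when records are passed to
#'   [run_pipeline()] directly).
#' @param output_dir Directory for attrition, classification and report
#'   files; created if missing.
#' @param location_lexicon,vaping_terms A [lexicon()] or path to a lexicon
#'   file; defaults to the bundled lexicons.
#' @param filter A [filter_config()].
#' @param classifier_mode `"multi_label"` or `"first_match"`.
#' @param keep_hashtag_words Keep hashtag words during normalization?
#' @param report_formats Subset of `c("csv", "markdown", "json")`.
#' @param strict Passed to [read_corpus()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, output_dir = NULL,
                            location_lexicon = NULL, vaping_terms = NULL,
                            filter = filter_config(),
                            classifier_mode = c("multi_label", "first_match"),
                            keep_hashtag_words = FALSE,
                            report_formats = c("csv", "markdown", "json"),
                            strict = FALSE) {
  classifier_mode <- match.arg(classifier_mode)
  assert_that(all(report_formats %in% c("csv", "markdown", "json")),
              "unknown report format",
              class = "vapescope_config_error")
  as_lex <- function(x, default) {
    if (is.null(x)) return(default())
    if (inherits(x, "vape_lexicon")) return(x)
    load_lexicon(x)
  }
  structure(list(
    input = input, output_dir = output_dir,
    location_lexicon = as_lex(location_lexicon, default_location_lexicon),
    vaping_terms = as_lex(vaping_terms, default_vaping_lexicon),
    filter = filter, classifier_mode = classifier_mode,
    keep_hashtag_words = isTRUE(keep_hashtag_words),
    report_formats = report_formats, strict = isTRUE(strict)
  ), class = "pipeline_config")
}

#' Run the full surveillance pipeline
#'
#' Reads the corpus, applies the six-stage exclusion cascade, gates on
#' vaping terms, classifies survivors into location categories, and computes
#' the prevalence table. When `config$output_dir` is set, writes
#' `attrition.csv` (stage, n_in, n_removed, n_out), `classified.jsonl`,
#' `report.{csv,md,json}` and `run_log.yaml` (config hash plus stage
#' counts). Deterministic given the configuration.
#'
#' @param config A [pipeline_config()].
#' @param records Optional corpus tibble, bypassing `config$input`.
#' @return List with `prevalence` (a `prevalence_table`), `reports` (the
#'   attrition tibble, including the vaping-gate and location-match stages),
#'   `classified` (the analytic-sample classification tibble), and
#'   `survivors` (records surviving the cascade).
#' @export
run_pipeline <- function(config, records = NULL) {
  assert_that(inherits(config, "pipeline_config"),
              "config must be a pipeline_config",
              class = "vapescope_config_error")
  if (is.null(records)) {
    assert_that(!is.null(config$input), "no input corpus configured",
                class = "vapescope_config_error")
    records <- read_corpus(config$input, strict = config$strict)
  }
  cascade <- run_filter_cascade(records, config$filter)
  survivors <- cascade$records

  classified <- classify_corpus(
    survivors,
    vaping_terms = config$vaping_terms,
    location_lexicon = config$location_lexicon,
    mode = config$classifier_mode,
    keep_hashtag_words = config$keep_hashtag_words
  )
  reports <- dplyr::bind_rows(
    cascade$reports,
    stage_report("vaping_gate_and_location_match",
                 nrow(survivors), nrow(classified))
  )
  assert_that(nrow(classified) > 0,
              "no posts survive the vaping gate and location match",
              class = "vapescope_data_error")
  prevalence <- compute_prevalence(
    classified, categories = names(config$location_lexicon$entries))

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$output_dir, f)
    write.csv(reports, out("attrition.csv"), row.names = FALSE)
    write_classified(classified, out("classified.jsonl"), format = "jsonl")
    ext <- c(csv = "report.csv", markdown = "report.md", json = "report.json")
    for (fmt in config$report_formats) {
      writeLines(render_report(prevalence, format = fmt), out(ext[[fmt]]))
    }
    log <- list(
      config_hash = config_hash(config[setdiff(names(config), "output_dir")]),
      n_input = nrow(records),
      stages = lapply(seq_len(nrow(reports)), function(i) {
        as.list(reports[i, c("stage", "n_in", "n_removed", "n_out")])
      }),
      analytic_sample = prevalence$n_total,
      n_users = prevalence$n_users
    )
    yaml::write_yaml(log, out("run_log.yaml"))
  }
  list(prevalence = prevalence, reports = reports,
       classified = classified, survivors = survivors)
}

#' Write a synthetic corpus plus its ground-truth sidecar
#'
#' Convenience wrapper for the `generate` CLI subcommand: writes the corpus
#' as JSONL and a YAML sidecar recording the spec and the realized
#' ground-truth tallies (contaminant counts and clean category counts).
#'
#' @param spec A [corpus_spec()].
#' @param path Destination JSONL path; the sidecar gets `.yaml` appended.
#' @return The generated corpus, invisibly.
#' @export
write_synthetic_corpus <- function(spec, path) {
  records <- generate_corpus(spec)
  write_corpus(records, path)
  kinds <- vapply(records$truth_labels, function(l) l$kind, character(1))
  truth <- mixture_truth(records)
  sidecar <- list(
    spec = list(n_posts = spec$n_posts, fracs = as.list(spec$fracs),
                category_mixture = as.list(spec$category_mixture),
                multi_label_rate = spec$multi_label_rate, seed = spec$seed),
    realized = list(
      contaminants = as.list(table(kinds)),
      clean_category_counts = as.list(
        setNames(truth$rows$n_posts, truth$rows$category)),
      n_clean = truth$n_total
    )
  )
  yaml::write_yaml(sidecar, paste0(path, ".yaml"))
  invisible(records)
}
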