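#' Pipeline configuration
#'
#' Bundles every tunable of the extraction and scoring pipeline. Unset
#' fields fall back to the embedded defaults (the published weights,
#' thresholds and keyword exemplars).
#'
#' @param research_types Article types that pass the research-only filter.
#' @param weights A `td_weights` (see [weight_config()]).
#' @param enzyme_terms Enzyme long forms for abbreviation rule G2.
#' @param disease_keywords,target_keywords,context_keywords Keyword lists
#'   for the abbreviation filter.
#' @param cutoff Ranking evaluation depth.
#' @param apply_min_occurrence Whether to apply the minimum-occurrence
#'   filter (disable to score every extracted record, e.g. for diagnostics).
#' @return A `td_pipeline_config`.
#' @export
pipeline_config <- function(research_types = c("research-article", "Research"),
                            weights = weight_config(),
                            enzyme_terms = character(0),
                            disease_keywords = default_disease_keywords(),
                            target_keywords = default_target_keywords(),
                            context_keywords = default_context_keywords(),
                            cutoff = 25L,
                            apply_min_occurrence = TRUE) {
  structure(
    list(research_types = research_types, weights = weights,
         enzyme_terms = enzyme_terms, disease_keywords = disease_keywords,
         target_keywords = target_keywords,
         context_keywords = context_keywords, cutoff = cutoff,
         apply_min_occurrence = apply_min_occurrence),
    class = "td_pipeline_config"
  )
}

#' Run the full extraction and scoring pipeline
#'
#' Stages, in fixed order: research-article filter, dictionary annotation,
#' abbreviation filter, sentence-level co-occurrence extraction, excluded-
#' section filter, aggregation, minimum-occurrence filter, scoring (CS2 for
#' full texts, CS1 with the batch boosting-up factor for abstracts).
#'
#' @param documents List of `td_document`.
#' @param target_lexicon,disease_lexicon Refined `td_lexicon` objects.
#' @param config A `td_pipeline_config`.
#' @return List with `evidence` (one row per (doc, target, disease):
#'   ids, `formula_used`, `s1`, `s2`, `boosting_up_factor`, `confidence`),
#'   `records` (the scored association records), `mentions` (post
#'   abbreviation filter), `decisions` (abbreviation filter decisions) and
#'   `report` (per-stage counts and the batch boosting-up factor).
#' @export
run_pipeline <- function(documents, target_lexicon, disease_lexicon,
                         config = pipeline_config()) {
  report <- list(n_documents_in = length(documents))

  research <- filter_article_type(documents, config$research_types)
  report$n_documents_research <- length(research)
  report$removed_by_type <- attr(research, "removed") %||% character(0)

  mentions <- annotate_corpus(research, target_lexicon, disease_lexicon)
  report$n_mentions_raw <- nrow(mentions)

  decisions <- NULL
  for (doc in research) {
    res <- filter_abbreviations(
      doc, mentions, target_lexicon, disease_lexicon,
      enzyme_terms = config$enzyme_terms,
      disease_keywords = config$disease_keywords,
      target_keywords = config$target_keywords,
      context_keywords = config$context_keywords
    )
    mentions <- res$mentions
    decisions <- dplyr::bind_rows(decisions, res$decisions)
  }
  report$n_mentions_filtered <- nrow(mentions)

  events <- extract_events(mentions, research)
  report$n_events <- nrow(events)
  events <- filter_excluded_sections(events)
  report$n_events_after_section_filter <- nrow(events)

  records <- aggregate_associations(events, mentions, research)
  report$n_records <- nrow(records)
  if (isTRUE(config$apply_min_occurrence)) {
    records <- filter_min_occurrence(records)
  }
  report$n_records_after_min_occurrence <- nrow(records)

  scores <- score_documents(records, config$weights)
  report$boosting_up_factor <- attr(scores, "boosting_up_factor")

  evidence <- scores |>
    dplyr::arrange(.data$target_id, .data$disease_id,
                   dplyr::desc(.data$confidence), .data$doc_id)
  list(evidence = evidence, records = records, mentions = mentions,
       decisions = decisions, report = report)
}

#' Write evidence as JSON lines
#'
#' One JSON object per scored (document, target, disease) triple, the
#' simplified analogue of the downloadable evidence format.
#'
#' @param evidence Evidence tibble from [run_pipeline()].
#' @param path Optional output file.
#' @return Character vector of JSON lines (invisibly when written).
#' @export
write_evidence_jsonl <- function(evidence, path = NULL) {
  lines <- vapply(seq_len(nrow(evidence)), function(i) {
    jsonlite::toJSON(as.list(evidence[i, ]), auto_unbox = TRUE, na = "null")
  }, character(1))
  if (!is.null(path)) {
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(lines))
  }
  lines
}
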