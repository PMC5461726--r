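empty_events <- function() {
  tibble::tibble(
    doc_id = character(0), target_id = character(0),
    disease_id = character(0), zone_label = character(0),
    sentence_index = integer(0), abstract_location_class = character(0)
  )
}

#' Extract sentence-level target-disease co-occurrence events
#'
#' One event per sentence per distinct (target identifier, disease
#' identifier) pair for which the sentence carries at least one mention of
#' each kind; mention multiplicity within the sentence does not multiply
#' events. Events in the abstract additionally carry the sentence-location
#' class (first_or_second / last / other) used by the abstract score.
#'
#' @param mentions Mention tibble (post abbreviation filter).
#' @param documents List of `td_document` the mentions came from (needed to
#'   locate the last abstract sentence).
#' @return Event tibble with columns `doc_id`, `target_id`, `disease_id`,
#'   `zone_label`, `sentence_index`, `abstract_location_class` (`NA` outside
#'   the abstract).
#' @export
extract_events <- function(mentions, documents) {
  if (nrow(mentions) == 0L) return(empty_events())
  abs_len <- abstract_lengths(documents)

  events <- mentions |>
    dplyr::distinct(.data$doc_id, .data$zone_label, .data$sentence_index,
                    .data$entity_kind, .data$identifier)
  targets <- events |>
    dplyr::filter(.data$entity_kind == "target") |>
    dplyr::rename(target_id = "identifier") |>
    dplyr::select(-"entity_kind")
  diseases <- events |>
    dplyr::filter(.data$entity_kind == "disease") |>
    dplyr::rename(disease_id = "identifier") |>
    dplyr::select(-"entity_kind")
  out <- dplyr::inner_join(
    targets, diseases,
    by = c("doc_id", "zone_label", "sentence_index"),
    relationship = "many-to-many"
  )
  if (nrow(out) == 0L) return(empty_events())
  out$abstract_location_class <- NA_character_
  in_abs <- out$zone_label == "abstract"
  if (any(in_abs)) {
    n <- abs_len[out$doc_id[in_abs]]
    out$abstract_location_class[in_abs] <- mapply(
      abstract_location_class, out$sentence_index[in_abs], n
    )
  }
  out |>
    dplyr::distinct() |>
    dplyr::select(dplyr::all_of(names(empty_events()))) |>
    dplyr::arrange(.data$doc_id, .data$target_id, .data$disease_id,
                   .data$zone_label, .data$sentence_index)
}

abstract_lengths <- function(documents) {
  out <- vapply(documents, function(d) {
    labels <- vapply(d$zones, `[[`, character(1), "label")
    nrow(d$zones[[which(labels == "abstract")]]$sentences)
  }, integer(1))
  stats::setNames(out, vapply(documents, `[[`, character(1), "doc_id"))
}

#' Keep only research articles
#'
#' Review articles, case reports and other non-research publication types
#' mostly restate known associations, so they are filtered out before
#' extraction. Documents with a missing article type are dropped (with a
#' warning) — the filter's intent is conservative.
#'
#' @param documents List of `td_document`.
#' @param research_types Article-type strings that count as research.
#' @return Filtered list, with attribute `removed` giving the dropped
#'   document ids.
#' @export
filter_article_type <- function(documents,
                                research_types = c("research-article", "Research")) {
  keep <- vapply(documents, function(d) {
    !is.na(d$article_type) && d$article_type %in% research_types
  }, logical(1))
  missing <- vapply(documents, function(d) is.na(d$article_type), logical(1))
  if (any(missing)) {
    warning("dropping ", sum(missing), " document(s) with missing article_type")
  }
  out <- documents[keep]
  attr(out, "removed") <- vapply(documents[!keep], `[[`, character(1), "doc_id")
  out
}

#' Drop events found in excluded sections
#'
#' Removes co-occurrence events whose zone is one of Methods, References,
#' Acknowledgement & Funding, Competing Interests, Author Contribution or
#' Supplementary Material.
#'
#' @param events Event tibble from [extract_events()].
#' @return Filtered event tibble.
#' @export
filter_excluded_sections <- function(events) {
  events[!(events$zone_label %in% excluded_zone_labels()), , drop = FALSE]
}

association_count_columns <- function() {
  c("count_title",
    "count_abs_first_or_second", "count_abs_last", "count_abs_other",
    paste0("count_", setdiff(zone_labels(), c("title", "abstract"))))
}

empty_records <- function() {
  counts <- stats::setNames(
    rep(list(integer(0)), length(association_count_columns())),
    association_count_columns()
  )
  tibble::as_tibble(c(
    list(doc_id = character(0), target_id = character(0),
         disease_id = character(0), is_fulltext = logical(0)),
    counts,
    list(count_abstract = integer(0), body_total = integer(0),
         gene_abstract_mentions = integer(0))
  ))
}

#' Aggregate events into per-document association records
#'
#' Tallies, for every (document, target, disease) triple with at least one
#' event, the co-occurrence counts by zone and — inside the abstract — by
#' sentence-location class, plus the number of target mentions in the
#' abstract (the gene-in-abstract term of the abstract score). These
#' records are the sole input to scoring.
#'
#' @param events Event tibble (normally post [filter_excluded_sections()]).
#' @param mentions Mention tibble for the same documents (for the
#'   gene-in-abstract mention count, which is mention-level, not
#'   sentence-level).
#' @param documents List of `td_document` (for the full-text flag).
#' @return Record tibble with one row per (doc, target, disease): identifier
#'   columns, `is_fulltext`, one `count_<zone>` column per zone (title and
#'   each body label), `count_abs_first_or_second` / `count_abs_last` /
#'   `count_abs_other`, their sum `count_abstract`, `body_total` (all zones
#'   except title and abstract) and `gene_abstract_mentions`.
#' @export
aggregate_associations <- function(events, mentions, documents) {
  if (nrow(events) == 0L) return(empty_records())
  ft <- stats::setNames(
    vapply(documents, `[[`, logical(1), "is_open_access_fulltext"),
    vapply(documents, `[[`, character(1), "doc_id")
  )

  keys <- dplyr::distinct(events, .data$doc_id, .data$target_id, .data$disease_id)
  zone_counts <- events |>
    dplyr::count(.data$doc_id, .data$target_id, .data$disease_id,
                 .data$zone_label) |>
    tidyr::pivot_wider(names_from = "zone_label", values_from = "n",
                       names_prefix = "count_", values_fill = 0L)
  loc_counts <- events |>
    dplyr::filter(.data$zone_label == "abstract") |>
    dplyr::count(.data$doc_id, .data$target_id, .data$disease_id,
                 .data$abstract_location_class) |>
    tidyr::pivot_wider(names_from = "abstract_location_class",
                       values_from = "n",
                       names_prefix = "count_abs_", values_fill = 0L)
  gene_abs <- mentions |>
    dplyr::filter(.data$entity_kind == "target",
                  .data$zone_label == "abstract") |>
    dplyr::count(.data$doc_id, target_id = .data$identifier,
                 name = "gene_abstract_mentions")

  rec <- keys |>
    dplyr::left_join(zone_counts, by = c("doc_id", "target_id", "disease_id")) |>
    dplyr::left_join(loc_counts, by = c("doc_id", "target_id", "disease_id")) |>
    dplyr::left_join(gene_abs, by = c("doc_id", "target_id"))

  for (col in c(association_count_columns(), "gene_abstract_mentions",
                "count_abstract")) {
    if (!col %in% names(rec)) rec[[col]] <- 0L
    rec[[col]][is.na(rec[[col]])] <- 0L
  }
  rec$count_abstract <- rec$count_abs_first_or_second + rec$count_abs_last +
    rec$count_abs_other
  body_cols <- paste0("count_", setdiff(zone_labels(), c("title", "abstract")))
  rec$body_total <- as.integer(rowSums(rec[, body_cols, drop = FALSE]))
  rec$is_fulltext <- unname(ft[rec$doc_id])
  rec |>
    dplyr::select(dplyr::all_of(names(empty_records()))) |>
    dplyr::arrange(.data$doc_id, .data$target_id, .data$disease_id)
}

#' Drop associations seen only once, deep in the body
#'
#' A pair that appears exactly once in the body of an article and never in
#' its title or abstract is likely incidental; such records are removed.
#' Abstract-only documents are unaffected (body total 0 with abstract
#' events passes).
#'
#' @param records Record tibble from [aggregate_associations()].
#' @return Filtered record tibble.
#' @export
filter_min_occurrence <- function(records) {
  if (nrow(records) == 0L) return(records)
  drop <- records$body_total == 1L & records$count_title == 0L &
    records$count_abstract == 0L
  records[!drop, , drop = FALSE]
}
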