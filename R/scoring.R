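#' Scoring weight configuration
#'
#' The default weights encode where the subject of a paper is stated rather
#' than reviewed: inside an abstract the last sentence (typically the
#' result) weighs 5, the first or second (typically background) 2 and the
#' rest 3; inside full text the title weighs 10, Results/Figure/Table 5,
#' Discussion/Conclusion 2, and Introduction/Case Study/Appendix/Other 1.
#' Each target mention in the abstract adds 0.2 to the abstract score.
#'
#' @param sentence_location_weights Named numeric for the abstract sentence
#'   location classes.
#' @param section_weights Named numeric for full-text zones (title included).
#' @param gene_abstract_coefficient Per-mention bonus for the target gene
#'   appearing in the abstract.
#' @return A `td_weights` list.
#' @export
weight_config <- function(sentence_location_weights = c(first_or_second = 2,
                                                        last = 5, other = 3),
                          section_weights = c(title = 10, results = 5,
                                              figure = 5, table = 5,
                                              discussion = 2, conclusion = 2,
                                              introduction = 1, case_study = 1,
                                              appendix = 1, other = 1),
                          gene_abstract_coefficient = 0.2) {
  stopifnot(
    all(sentence_location_weights > 0), all(section_weights > 0),
    all(c("first_or_second", "last", "other") %in%
          names(sentence_location_weights))
  )
  structure(
    list(
      sentence_location_weights = sentence_location_weights,
      section_weights = section_weights,
      gene_abstract_coefficient = gene_abstract_coefficient
    ),
    class = "td_weights"
  )
}

#' Abstract score S1
#'
#' Weighted sum of the abstract co-occurrence counts by sentence location,
#' plus the gene-in-abstract bonus:
#' `S1 = sum_i w_loc(i) * n_pair(i) + coef * n_gene_mentions_in_abstract`.
#'
#' @param records Record tibble (rows from [aggregate_associations()]).
#' @param weights A `td_weights`.
#' @return Numeric vector, one score per record row.
#' @export
score_s1 <- function(records, weights = weight_config()) {
  w <- weights$sentence_location_weights
  w[["first_or_second"]] * records$count_abs_first_or_second +
    w[["last"]] * records$count_abs_last +
    w[["other"]] * records$count_abs_other +
    weights$gene_abstract_coefficient * records$gene_abstract_mentions
}

#' Body score S2
#'
#' Weighted sum of co-occurrence counts over the non-abstract zones of a
#' full-text article: `S2 = sum_z w_sec(z) * n_pair(z)`. The abstract is
#' scored by S1 and excluded here; the title is included with its section
#' weight. Zones excluded from extraction contribute nothing because their
#' events were filtered upstream.
#'
#' @inheritParams score_s1
#' @return Numeric vector, one score per record row.
#' @export
score_s2 <- function(records, weights = weight_config()) {
  w <- weights$section_weights
  out <- numeric(nrow(records))
  for (zone in names(w)) {
    col <- paste0("count_", zone)
    if (col %in% names(records)) out <- out + w[[zone]] * records[[col]]
  }
  out
}

#' Boosting-up factor
#'
#' The median of all open-access full-text body scores (S2) in the current
#' batch. Added to every abstract-only confidence score to put CS1 on the
#' same scale as CS2. An empty batch yields 0.
#'
#' @param body_scores Numeric vector of S2 values for the batch's OA
#'   full-text records.
#' @return Scalar median (0 for empty input).
#' @export
boosting_up_factor <- function(body_scores) {
  body_scores <- body_scores[!is.na(body_scores)]
  if (length(body_scores) == 0L) return(0)
  stats::median(body_scores)
}

score_tibble <- function(records, s1, s2, boost, confidence, formula) {
  tibble::tibble(
    doc_id = records$doc_id,
    target_id = records$target_id,
    disease_id = records$disease_id,
    s1 = s1,
    s2 = s2,
    boosting_up_factor = boost,
    confidence = confidence,
    formula_used = formula
  )
}

#' Confidence score CS1 (abstract-only documents)
#'
#' `CS1 = w_title * n_title_pair + S1 + boosting-up factor`. The title term
#' uses the same weight (10) as a full-text title.
#'
#' @param records Record rows for abstract-only documents.
#' @param weights A `td_weights`.
#' @param boost Batch boosting-up factor (see [boosting_up_factor()]).
#' @return `DocumentScore` tibble: ids, `s1`, `s2` (NA), `boosting_up_factor`,
#'   `confidence`, `formula_used = "CS1"`.
#' @export
score_cs1 <- function(records, weights = weight_config(), boost = 0) {
  if (any(records$is_fulltext)) {
    stop("CS1 applies to abstract-only documents; got full-text record(s): ",
         paste(records$doc_id[records$is_fulltext], collapse = ", "))
  }
  s1 <- score_s1(records, weights)
  confidence <- weights$section_weights[["title"]] * records$count_title +
    s1 + boost
  score_tibble(records, s1, NA_real_, boost, confidence, "CS1")
}

#' Confidence score CS2 (full-text documents)
#'
#' `CS2 = S1 + S2`: abstract mentions flow through S1, everything else
#' (title included) through S2.
#'
#' @param records Record rows for full-text documents.
#' @param weights A `td_weights`.
#' @return `DocumentScore` tibble with `formula_used = "CS2"`.
#' @export
score_cs2 <- function(records, weights = weight_config()) {
  if (any(!records$is_fulltext)) {
    stop("CS2 applies to full-text documents; got abstract-only record(s): ",
         paste(records$doc_id[!records$is_fulltext], collapse = ", "))
  }
  s1 <- score_s1(records, weights)
  s2 <- score_s2(records, weights)
  score_tibble(records, s1, s2, NA_real_, s1 + s2, "CS2")
}

#' Score a batch of association records
#'
#' Computes CS2 for every full-text record, takes the median of their S2
#' values as the batch boosting-up factor, and computes CS1 (with that
#' boost) for every abstract-only record.
#'
#' @param records Record tibble from [aggregate_associations()].
#' @param weights A `td_weights`.
#' @return `DocumentScore` tibble for all records, with attribute
#'   `boosting_up_factor`.
#' @export
score_documents <- function(records, weights = weight_config()) {
  ft <- records[records$is_fulltext, , drop = FALSE]
  ab <- records[!records$is_fulltext, , drop = FALSE]
  ft_scores <- if (nrow(ft) > 0L) score_cs2(ft, weights) else NULL
  boost <- boosting_up_factor(if (is.null(ft_scores)) numeric(0) else ft_scores$s2)
  ab_scores <- if (nrow(ab) > 0L) score_cs1(ab, weights, boost) else NULL
  out <- dplyr::bind_rows(ft_scores, ab_scores)
  if (is.null(out) || nrow(out) == 0L) {
    out <- score_tibble(empty_records(), numeric(0), numeric(0), numeric(0),
                        numeric(0), character(0))
  }
  attr(out, "boosting_up_factor") <- boost
  out
}

#' Rank documents for one target-disease association
#'
#' Orders the scored documents for the given pair by descending confidence;
#' ties are broken by ascending document id so output is deterministic.
#'
#' @param scores `DocumentScore` tibble.
#' @param target_id,disease_id The association to rank documents for.
#' @return Permutation of the matching input rows, best document first.
#' @export
rank_documents <- function(scores, target_id, disease_id) {
  sel <- scores[scores$target_id == target_id &
                  scores$disease_id == disease_id, , drop = FALSE]
  sel[order(-sel$confidence, sel$doc_id), , drop = FALSE]
}
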