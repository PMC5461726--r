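#' Default keyword lists for the abbreviation filter
#'
#' Disease keywords are words that mark a long form as describing a disease
#' (rule D2); target keywords mark a long form as describing a gene or
#' protein (rule G3); context keywords are the molecular-biology terms whose
#' sentence-level co-presence with the short form and a disease mention
#' rescues a gene abbreviation (rule G4). All lists are configurable — the
#' published exemplars are included verbatim and the tails are this
#' package's defaults.
#'
#' @name abbrev_keywords
NULL

#' @rdname abbrev_keywords
#' @export
default_disease_keywords <- function() {
  c("disease", "disorder", "syndrome", "defect", "deficiency", "cancer",
    "carcinoma", "tumor", "tumour", "infection")
}

#' @rdname abbrev_keywords
#' @export
default_target_keywords <- function() {
  c("factor", "receptor", "gene", "protein", "enzyme", "kinase",
    "antigen", "ligand")
}

#' @rdname abbrev_keywords
#' @export
default_context_keywords <- function() {
  c("mutation", "SNP", "variation", "gene", "inhibit", "variant",
    "polymorphism", "mutant", "isoform", "protein", "enzyme", "activate",
    "antibody", "transcription", "tumor suppressor", "express",
    "overexpress", "regulator", "receptor", "oncogene")
}

empty_candidates <- function() {
  tibble::tibble(
    doc_id = character(0), zone_label = character(0),
    sentence_index = integer(0), short_form = character(0),
    long_form = character(0), entity_kind = character(0),
    identifiers = list()
  )
}

# is `tok` a valid short form: all-uppercase, length < 6, at least one letter
is_short_form <- function(tok) {
  nzchar(tok) & nchar(tok) < 6L & tok == toupper(tok) &
    stringr::str_detect(tok, "\\p{Lu}")
}

#' Find abbreviation candidates in a document
#'
#' Scans every sentence for the pattern "long form (XYZ)": a parenthesised
#' token that is all-uppercase, shorter than six characters, and annotated
#' as a target or disease mention at that position. The potential long form
#' is the up-to-N+1 words immediately before the parenthesis, N being the
#' short form's length (a Schwartz–Hearst-style window).
#'
#' @param document A `td_document`.
#' @param mentions Mention tibble from [annotate()] for the same document.
#' @return Tibble of candidates with columns `doc_id`, `zone_label`,
#'   `sentence_index`, `short_form`, `long_form`, `entity_kind` and a
#'   list-column `identifiers` (the identifiers the short form maps to).
#'   One row per distinct (short form, entity kind) per document: the first
#'   pattern occurrence supplies the long form, identifiers are pooled.
#' @export
find_candidates <- function(document, mentions) {
  stopifnot(inherits(document, "td_document"))
  out <- empty_candidates()
  doc_mentions <- mentions[mentions$doc_id == document$doc_id, , drop = FALSE]
  if (nrow(doc_mentions) == 0L) return(out)

  for (zone in document$zones) {
    sents <- zone$sentences
    for (si in seq_len(nrow(sents))) {
      sentence <- sents$text[si]
      locs <- stringr::str_locate_all(sentence, "\\(([^()\\s]{1,5})\\)")[[1]]
      if (nrow(locs) == 0L) next
      for (j in seq_len(nrow(locs))) {
        tok_start <- locs[j, "start"] + 1L
        tok_end <- locs[j, "end"] - 1L
        tok <- substr(sentence, tok_start, tok_end)
        if (!is_short_form(tok)) next
        # annotated as target or disease at exactly this span?
        m <- doc_mentions[
          doc_mentions$zone_label == zone$label &
            doc_mentions$sentence_index == sents$index_in_zone[si] &
            doc_mentions$start == tok_start - 1L &
            doc_mentions$end == tok_end, , drop = FALSE
        ]
        if (nrow(m) == 0L) next
        long_form <- extract_long_form(sentence, locs[j, "start"], nchar(tok))
        for (kind in unique(m$entity_kind)) {
          out <- dplyr::bind_rows(out, tibble::tibble(
            doc_id = document$doc_id,
            zone_label = zone$label,
            sentence_index = sents$index_in_zone[si],
            short_form = tok,
            long_form = long_form,
            entity_kind = kind,
            identifiers = list(unique(m$identifier[m$entity_kind == kind]))
          ))
        }
      }
    }
  }
  if (nrow(out) <= 1L) return(out)
  # one candidate per (short form, kind); pool identifiers, keep first long form
  out |>
    dplyr::group_by(.data$doc_id, .data$short_form, .data$entity_kind) |>
    dplyr::summarise(
      zone_label = dplyr::first(.data$zone_label),
      sentence_index = dplyr::first(.data$sentence_index),
      long_form = dplyr::first(.data$long_form),
      identifiers = list(unique(unlist(.data$identifiers))),
      .groups = "drop"
    ) |>
    dplyr::select(dplyr::all_of(names(empty_candidates())))
}

# up to n_short + 1 whitespace-delimited words immediately before the "("
extract_long_form <- function(sentence, paren_start, n_short) {
  before <- trimws(substr(sentence, 1L, paren_start - 1L))
  if (!nzchar(before)) return("")
  words <- stringr::str_split(before, "\\s+")[[1]]
  k <- min(length(words), n_short + 1L)
  lf <- paste(utils::tail(words, k), collapse = " ")
  # strip leading/trailing punctuation remnants
  stringr::str_remove_all(lf, "^[[:punct:]]+|[,;:]+$")
}

decision_row <- function(candidate, kept, rule) {
  tibble::tibble(
    doc_id = candidate$doc_id,
    short_form = candidate$short_form,
    entity_kind = candidate$entity_kind,
    long_form = candidate$long_form,
    kept = kept,
    rule_fired = rule
  )
}

#' Decide whether a disease abbreviation candidate is genuine
#'
#' A disease short form is kept when (D1) any dictionary surface sharing one
#' of the candidate's identifiers — i.e. a known long form of that disease —
#' occurs in the document text, or (D2) the extracted long form contains a
#' disease keyword. Otherwise it is a false positive (like "ALS" glossed as
#' "advanced life support") and will be screened out.
#'
#' @param candidate One-row candidate tibble (see [find_candidates()]).
#' @param document The `td_document` it came from.
#' @param disease_lexicon `td_lexicon` of kind disease.
#' @param disease_keywords Character vector; see
#'   [default_disease_keywords()].
#' @return One-row decision tibble with columns `doc_id`, `short_form`,
#'   `entity_kind`, `long_form`, `kept`, `rule_fired` ("D1", "D2" or
#'   "none"); the first rule that fires is recorded.
#' @export
filter_disease_candidate <- function(candidate, document, disease_lexicon,
                                     disease_keywords = default_disease_keywords()) {
  stopifnot(identical(candidate$entity_kind, "disease"))
  ids <- unlist(candidate$identifiers)
  doc_lc <- tolower(document_text(document))
  long_forms <- disease_lexicon$entries$surface[
    disease_lexicon$entries$identifier %in% ids &
      tolower(disease_lexicon$entries$surface) != tolower(candidate$short_form)
  ]
  d1 <- length(long_forms) > 0L &&
    any(stringr::str_detect(doc_lc, stringr::fixed(tolower(long_forms))))
  if (d1) return(decision_row(candidate, TRUE, "D1"))
  d2 <- any(stringr::str_detect(tolower(candidate$long_form),
                                stringr::fixed(tolower(disease_keywords))))
  if (d2) return(decision_row(candidate, TRUE, "D2"))
  decision_row(candidate, FALSE, "none")
}

#' Decide whether a gene/protein abbreviation candidate is genuine
#'
#' A gene short form is kept when any of four rules fires, checked in order:
#' G1 — the short form occurs more than 3 times in the document body
#' (open-access full text only); G2 — the long form matches a dictionary or
#' enzyme name exactly (case-insensitive); G3 — the long form's last word
#' ends in -ase/-ases, or the long form contains a target keyword; G4 — at
#' least 3 sentences (full text) or 2 (abstract-only records) contain a
#' context keyword together with the short form and a disease mention.
#'
#' @param candidate One-row candidate tibble of kind target.
#' @param document The `td_document` it came from.
#' @param target_lexicon `td_lexicon` of kind target.
#' @param enzyme_terms Character vector of enzyme names (long forms).
#' @param target_keywords,context_keywords See [default_target_keywords()]
#'   and [default_context_keywords()].
#' @param mentions Mention tibble for this document (needed by G4's
#'   disease-mention test).
#' @return One-row decision tibble (`rule_fired` in "G1".."G4" or "none").
#' @export
filter_gene_candidate <- function(candidate, document, target_lexicon,
                                  enzyme_terms = character(0),
                                  target_keywords = default_target_keywords(),
                                  context_keywords = default_context_keywords(),
                                  mentions = empty_mentions()) {
  stopifnot(identical(candidate$entity_kind, "target"))
  sf <- candidate$short_form

  # G1: short form frequent in the body of OA full text
  if (isTRUE(document$is_open_access_fulltext)) {
    body <- document$zones[!vapply(document$zones, `[[`, character(1), "label") %in%
                             c("title", "abstract")]
    n_occ <- sum(vapply(body, function(z) {
      locs <- stringr::str_locate_all(z$text, stringr::fixed(sf))[[1]]
      if (nrow(locs) == 0L) return(0L)
      sum(vapply(seq_len(nrow(locs)), function(j) {
        at_word_boundary(z$text, locs[j, "start"], locs[j, "end"])
      }, logical(1)))
    }, numeric(1)))
    if (n_occ > 3) return(decision_row(candidate, TRUE, "G1"))
  }

  # G2: the long form matches a known target or enzyme name. The extraction
  # window may start a word early, so every trailing word sequence of the
  # window is tried (shortest-valid-long-form convention).
  lf_lc <- tolower(candidate$long_form)
  known <- tolower(c(target_lexicon$entries$surface, enzyme_terms))
  words <- stringr::str_split(lf_lc, "\\s+")[[1]]
  suffixes <- vapply(seq_along(words), function(k) {
    paste(words[k:length(words)], collapse = " ")
  }, character(1))
  if (nzchar(lf_lc) && any(suffixes %in% known)) {
    return(decision_row(candidate, TRUE, "G2"))
  }

  # G3: -ase/-ases suffix or a target keyword in the long form
  last_word <- stringr::str_extract(lf_lc, "[\\p{L}\\p{N}-]+$")
  g3 <- (!is.na(last_word) &&
           stringr::str_detect(last_word, "ases?$")) ||
    any(stringr::str_detect(lf_lc, stringr::fixed(tolower(target_keywords))))
  if (g3) return(decision_row(candidate, TRUE, "G3"))

  # G4: enough sentences pair the short form with a context keyword and a
  # disease mention
  threshold <- if (isTRUE(document$is_open_access_fulltext)) 3L else 2L
  doc_mentions <- mentions[mentions$doc_id == document$doc_id &
                             mentions$entity_kind == "disease", , drop = FALSE]
  n_support <- 0L
  for (zone in document$zones) {
    sents <- zone$sentences
    for (si in seq_len(nrow(sents))) {
      sentence <- sents$text[si]
      if (!stringr::str_detect(sentence, stringr::fixed(sf))) next
      if (!any(stringr::str_detect(tolower(sentence),
                                   stringr::fixed(tolower(context_keywords))))) next
      has_disease <- any(
        doc_mentions$zone_label == zone$label &
          doc_mentions$sentence_index == sents$index_in_zone[si]
      )
      if (has_disease) n_support <- n_support + 1L
    }
  }
  if (n_support >= threshold) return(decision_row(candidate, TRUE, "G4"))
  decision_row(candidate, FALSE, "none")
}

#' Apply abbreviation filter decisions to a mention list
#'
#' For every dropped candidate, removes all mentions in that document whose
#' surface equals the short form and whose entity kind matches — the
#' abbreviation is judged a false positive for the whole document. Kept
#' candidates leave mentions untouched. Never adds mentions.
#'
#' @param mentions Mention tibble.
#' @param decisions Decision tibble (rows from [filter_disease_candidate()]
#'   / [filter_gene_candidate()]); at most one decision per
#'   (doc_id, short_form, entity_kind).
#' @return Filtered mention tibble (a subset of the input rows).
#' @export
apply_decisions <- function(mentions, decisions) {
  if (is.null(decisions) || nrow(decisions) == 0L) return(mentions)
  dup <- decisions |>
    dplyr::count(.data$doc_id, .data$short_form, .data$entity_kind) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    stop("conflicting decisions for: ",
         paste(dup$doc_id, dup$short_form, dup$entity_kind, collapse = "; "))
  }
  dropped <- decisions[!decisions$kept, , drop = FALSE]
  if (nrow(dropped) == 0L) return(mentions)
  keep <- rep(TRUE, nrow(mentions))
  for (i in seq_len(nrow(dropped))) {
    keep <- keep & !(
      mentions$doc_id == dropped$doc_id[i] &
        mentions$surface == dropped$short_form[i] &
        mentions$entity_kind == dropped$entity_kind[i]
    )
  }
  mentions[keep, , drop = FALSE]
}

#' Run the full abbreviation filter over one document
#'
#' Finds candidates, decides each with the disease or gene rule set, and
#' applies the decisions to the mention list.
#'
#' @inheritParams filter_gene_candidate
#' @param disease_lexicon,disease_keywords Passed to
#'   [filter_disease_candidate()].
#' @return List with `mentions` (filtered) and `decisions` (tibble).
#' @export
filter_abbreviations <- function(document, mentions, target_lexicon,
                                 disease_lexicon,
                                 enzyme_terms = character(0),
                                 disease_keywords = default_disease_keywords(),
                                 target_keywords = default_target_keywords(),
                                 context_keywords = default_context_keywords()) {
  candidates <- find_candidates(document, mentions)
  if (nrow(candidates) == 0L) {
    return(list(mentions = mentions, decisions = NULL))
  }
  decisions <- purrr::map_dfr(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, , drop = FALSE]
    if (cand$entity_kind == "disease") {
      filter_disease_candidate(cand, document, disease_lexicon,
                               disease_keywords)
    } else {
      filter_gene_candidate(cand, document, target_lexicon, enzyme_terms,
                            target_keywords, context_keywords, mentions)
    }
  })
  list(
    mentions = apply_decisions(mentions, decisions),
    decisions = decisions
  )
}
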