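#' @keywords internal
empty_mentions <- function() {
  tibble::tibble(
    doc_id = character(0), zone_label = character(0),
    sentence_index = integer(0), start = integer(0), end = integer(0),
    entity_kind = character(0), identifier = character(0),
    surface = character(0)
  )
}

# Word characters for boundary purposes: Unicode letters (including Greek
# symbols) and digits. Hyphens are word-internal: a match may not start or
# end immediately inside a hyphenated token.
is_word_char <- function(ch) {
  nzchar(ch) & stringr::str_detect(ch, "[\\p{L}\\p{N}]")
}

# start/end are 1-based inclusive positions of a candidate match in `text`
at_word_boundary <- function(text, start, end) {
  n <- nchar(text)
  before <- if (start > 1L) substr(text, start - 1L, start - 1L) else ""
  before2 <- if (start > 2L) substr(text, start - 2L, start - 2L) else ""
  after <- if (end < n) substr(text, end + 1L, end + 1L) else ""
  after2 <- if (end + 1L < n) substr(text, end + 2L, end + 2L) else ""
  start_ok <- !is_word_char(before) &&
    !(before == "-" && is_word_char(before2))
  end_ok <- !is_word_char(after) &&
    !(after == "-" && is_word_char(after2))
  start_ok && end_ok
}

# Gene symbols are short and all-caps; for those, case matters (the protein
# "WAS" must not match the English word "was"). Everything else matches
# case-insensitively.
surface_case_sensitive <- function(surface) {
  stringr::str_length(surface) <= 5L &
    surface == toupper(surface) &
    stringr::str_detect(surface, "\\p{Lu}")
}

# all word-boundary occurrences of each lexicon surface in one sentence
locate_surface_matches <- function(sentence, surfaces) {
  if (length(surfaces) == 0L) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          surface = character(0)))
  }
  sens <- surface_case_sensitive(surfaces)
  sentence_lc <- tolower(sentence)
  rows <- purrr::map_dfr(seq_along(surfaces), function(i) {
    s <- surfaces[[i]]
    hay <- if (sens[[i]]) sentence else sentence_lc
    needle <- if (sens[[i]]) s else tolower(s)
    locs <- stringr::str_locate_all(hay, stringr::fixed(needle))[[1]]
    if (nrow(locs) == 0L) return(NULL)
    keep <- vapply(seq_len(nrow(locs)), function(j) {
      at_word_boundary(sentence, locs[j, "start"], locs[j, "end"])
    }, logical(1))
    locs <- locs[keep, , drop = FALSE]
    if (nrow(locs) == 0L) return(NULL)
    tibble::tibble(start = locs[, "start"], end = locs[, "end"], surface = s)
  })
  if (nrow(rows) == 0L) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          surface = character(0)))
  }
  rows
}

# longest-match, left-to-right, non-overlapping (within one entity kind)
resolve_matches <- function(matches) {
  if (nrow(matches) == 0L) return(matches)
  matches <- matches[order(matches$start, -matches$end), , drop = FALSE]
  last_end <- 0L
  keep <- logical(nrow(matches))
  for (i in seq_len(nrow(matches))) {
    if (matches$start[i] > last_end) {
      keep[i] <- TRUE
      last_end <- matches$end[i]
    }
  }
  matches[keep, , drop = FALSE]
}

#' Annotate target and disease mentions in a document
#'
#' Dictionary matcher over the sentence-split document model. Matching is
#' longest-match, left-to-right and word-boundary anchored (alphanumeric
#' runs with internal hyphens; Greek symbols are word characters). Short
#' all-uppercase surfaces (length <= 5) match case-sensitively, everything
#' else case-insensitively. Within one entity kind matches never overlap;
#' a target and a disease match may cover the same span (one mention per
#' kind). A surface mapped to several identifiers yields one mention per
#' identifier — ambiguity is resolved downstream by the abbreviation filter,
#' not here.
#'
#' @param document A `td_document`.
#' @param target_lexicon,disease_lexicon `td_lexicon` objects of matching
#'   entity kinds.
#' @return Tibble of mentions with columns `doc_id`, `zone_label`,
#'   `sentence_index`, `start`, `end` (0-based half-open within sentence),
#'   `entity_kind`, `identifier`, `surface`.
#' @export
annotate <- function(document, target_lexicon, disease_lexicon) {
  stopifnot(inherits(document, "td_document"),
            inherits(target_lexicon, "td_lexicon"),
            inherits(disease_lexicon, "td_lexicon"))
  if (!identical(target_lexicon$entity_kind, "target")) {
    stop("`target_lexicon` has entity_kind '", target_lexicon$entity_kind, "'")
  }
  if (!identical(disease_lexicon$entity_kind, "disease")) {
    stop("`disease_lexicon` has entity_kind '", disease_lexicon$entity_kind, "'")
  }

  lexicons <- list(target = target_lexicon, disease = disease_lexicon)
  out <- list()
  for (zone in document$zones) {
    sents <- zone$sentences
    for (si in seq_len(nrow(sents))) {
      sentence <- sents$text[si]
      for (kind in names(lexicons)) {
        entries <- lexicons[[kind]]$entries
        hits <- locate_surface_matches(sentence, unique(entries$surface))
        hits <- resolve_matches(hits)
        if (nrow(hits) == 0L) next
        for (h in seq_len(nrow(hits))) {
          ids <- entries$identifier[entries$surface == hits$surface[h]]
          out[[length(out) + 1L]] <- tibble::tibble(
            doc_id = document$doc_id,
            zone_label = zone$label,
            sentence_index = sents$index_in_zone[si],
            start = hits$start[h] - 1L,
            end = hits$end[h],
            entity_kind = kind,
            identifier = unique(ids),
            surface = substr(sentence, hits$start[h], hits$end[h])
          )
        }
      }
    }
  }
  if (length(out) == 0L) return(empty_mentions())
  dplyr::bind_rows(out)
}

#' Annotate a list of documents
#'
#' @param documents List of `td_document`.
#' @inheritParams annotate
#' @return Tibble of mentions across all documents (see [annotate()]).
#' @export
annotate_corpus <- function(documents, target_lexicon, disease_lexicon) {
  if (length(documents) == 0L) return(empty_mentions())
  dplyr::bind_rows(lapply(documents, annotate,
                          target_lexicon = target_lexicon,
                          disease_lexicon = disease_lexicon))
}

#' Write mentions as TSV
#'
#' @param mentions Mention tibble from [annotate()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mentions_tsv <- function(mentions, path) {
  utils::write.table(mentions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
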