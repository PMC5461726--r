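#' Zone labels of the document model
#'
#' Canonical set of zone labels. `title` and `abstract` occur at most once
#' per document; everything else is a body zone. Figure and table captions
#' are body zones in their own right because they carry their own section
#' weight.
#'
#' @return Character vector of the 17 labels.
#' @export
zone_labels <- function() {
  c(
    "title", "abstract", "introduction", "methods", "results", "figure",
    "table", "discussion", "conclusion", "case_study", "appendix",
    "references", "acknowledgement_funding", "competing_interests",
    "author_contribution", "supplementary", "other"
  )
}

#' Zones excluded from association extraction
#'
#' Co-occurrences found in these zones are discarded: boilerplate and
#' citation-heavy sections (Methods, References, Acknowledgement & Funding,
#' Competing Interests, Author Contribution, Supplementary Material) name
#' genes and diseases for reasons unrelated to the article's findings.
#'
#' @return Character vector of excluded labels.
#' @export
excluded_zone_labels <- function() {
  c("methods", "references", "acknowledgement_funding",
    "competing_interests", "author_contribution", "supplementary")
}

# Heading keyword table, in precedence order: the first label whose keyword
# matches wins, so "Results and Discussion" resolves to results.
section_keyword_table <- function() {
  list(
    results = c("result", "findings"),
    discussion = "discussion",
    conclusion = c("conclusion", "concluding remarks"),
    methods = c("method", "materials", "experimental procedure",
                "study design", "patients and"),
    introduction = c("introduction", "background"),
    case_study = c("case study", "case report", "case presentation"),
    appendix = "appendix",
    references = c("reference", "bibliography", "literature cited"),
    acknowledgement_funding = c("acknowledg", "funding", "financial support"),
    competing_interests = c("competing interest", "conflict of interest",
                            "declaration of interest"),
    author_contribution = c("author contribution", "authors' contribution",
                            "contribution of author"),
    supplementary = c("supplement", "additional file", "supporting information")
  )
}

#' Classify a section heading into a zone label
#'
#' Case-insensitive keyword classifier with fixed first-match precedence
#' (results > discussion > conclusion > methods > introduction > case_study >
#' appendix > references > acknowledgement_funding > competing_interests >
#' author_contribution > supplementary). Unrecognised or empty headings map
#' to `other`. Total and deterministic.
#'
#' @param heading Character vector of headings.
#' @return Character vector of zone labels, same length as `heading`.
#' @export
#' @examples
#' tag_section(c("MATERIALS AND METHODS", "Results and Discussion", ""))
tag_section <- function(heading) {
  tbl <- section_keyword_table()
  vapply(heading, function(h) {
    if (is.na(h) || !nzchar(trimws(h))) return("other")
    h <- tolower(h)
    for (label in names(tbl)) {
      if (any(stringr::str_detect(h, stringr::fixed(tbl[[label]])))) {
        return(label)
      }
    }
    "other"
  }, character(1), USE.NAMES = FALSE)
}

# Tokens that end with "." without terminating a sentence.
sentence_abbreviations <- function() {
  c("fig", "figs", "eq", "eqs", "ref", "refs", "al", "e.g", "i.e", "cf",
    "vs", "etc", "ca", "approx", "no", "nos", "dr", "prof", "st", "jr",
    "inc", "resp")
}

#' Split zone text into sentences
#'
#' Regex-based splitter: a run of `.`, `!` or `?` followed by whitespace ends
#' a sentence unless the token before it is on a short abbreviation exception
#' list ("Fig.", "et al.", "e.g." and similar). Offsets are 0-based,
#' half-open, into the zone text.
#'
#' @param zone_text Character scalar (may be empty).
#' @return Tibble with columns `text`, `index_in_zone` (0-based) and
#'   `char_start` (0-based offset of the sentence's first character in
#'   `zone_text`). Zero rows for empty/whitespace input.
#' @export
#' @examples
#' split_sentences("IGF1 (see Fig. 2) is elevated. Controls were normal.")
split_sentences <- function(zone_text) {
  empty <- tibble::tibble(
    text = character(0), index_in_zone = integer(0), char_start = integer(0)
  )
  if (is.na(zone_text) || !nzchar(trimws(zone_text))) return(empty)

  n <- nchar(zone_text)
  # candidate boundaries: terminator run then whitespace
  locs <- stringr::str_locate_all(zone_text, "[.!?]+(?=\\s)")[[1]]
  abbrevs <- sentence_abbreviations()
  ends <- integer(0)   # 1-based index of last char of each sentence
  for (i in seq_len(nrow(locs))) {
    s <- locs[i, "start"]; e <- locs[i, "end"]
    # token immediately before the terminator run
    before <- substr(zone_text, 1L, s - 1L)
    tok <- stringr::str_extract(before, "[\\p{L}\\p{N}.]+$")
    if (!is.na(tok) && tolower(tok) %in% abbrevs) next
    ends <- c(ends, e)
  }
  ends <- c(ends, n)
  ends <- unique(ends)

  out <- empty
  start <- 1L
  for (e in ends) {
    chunk <- substr(zone_text, start, e)
    lead_ws <- stringr::str_length(stringr::str_extract(chunk, "^\\s*"))
    text <- trimws(chunk)
    if (nzchar(text)) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        text = text,
        index_in_zone = nrow(out),
        char_start = start - 1L + lead_ws
      ))
    }
    start <- e + 1L
  }
  out$index_in_zone <- seq_len(nrow(out)) - 1L
  out
}

new_zone <- function(label, original_heading, text) {
  stopifnot(label %in% zone_labels())
  list(
    label = label,
    original_heading = original_heading %||% "",
    text = text %||% "",
    sentences = split_sentences(text %||% "")
  )
}

#' Construct a document
#'
#' Builds a `td_document` from its parts: a title, an abstract, optional body
#' sections (classified with [tag_section()]) and optional figure/table
#' captions, sentence-splitting every zone.
#'
#' @param doc_id Document identifier (PMID/PMCID-like string).
#' @param article_type Publication type string, e.g. `"research-article"`,
#'   `"review"`.
#' @param title,abstract Character scalars (either may be empty).
#' @param sections List of `list(heading =, text =)` body sections, in order.
#' @param captions List of `list(kind = "figure"|"table", text =)`.
#' @param open_access Logical; whether the full text is licensed for mining.
#'   A document counts as open-access full text only when it also has body
#'   zones.
#' @return A `td_document`.
#' @export
new_document <- function(doc_id, article_type = "research-article",
                         title = "", abstract = "",
                         sections = list(), captions = list(),
                         open_access = length(sections) > 0) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L, nzchar(doc_id))
  zones <- list(new_zone("title", "", title), new_zone("abstract", "", abstract))
  for (sec in sections) {
    zones <- c(zones, list(new_zone(
      tag_section(sec$heading %||% ""), sec$heading %||% "", sec$text %||% ""
    )))
  }
  for (cap in captions) {
    kind <- match.arg(cap$kind, c("figure", "table"))
    zones <- c(zones, list(new_zone(kind, "", cap$text %||% "")))
  }
  has_body <- length(zones) > 2L
  structure(
    list(
      doc_id = doc_id,
      article_type = article_type %||% NA_character_,
      is_open_access_fulltext = isTRUE(open_access) && has_body,
      zones = zones
    ),
    class = "td_document"
  )
}

#' @export
print.td_document <- function(x, ...) {
  cat(sprintf(
    "<td_document> %s [%s]%s: %d zones (%s)\n",
    x$doc_id, x$article_type,
    if (x$is_open_access_fulltext) " OA full text" else "",
    length(x$zones),
    paste(vapply(x$zones, `[[`, character(1), "label"), collapse = ", ")
  ))
  invisible(x)
}

#' Full document text
#'
#' Concatenates all zone texts (used e.g. by the abbreviation filter to test
#' whether a dictionary long form occurs anywhere in the document).
#'
#' @param document A `td_document`.
#' @return Character scalar.
#' @export
document_text <- function(document) {
  paste(vapply(document$zones, `[[`, character(1), "text"), collapse = " ")
}

#' Classify an abstract sentence index into its location class
#'
#' The abstract scoring weights distinguish the first or second sentence
#' (typically background), the last sentence (typically the result), and
#' everything in between. The last sentence wins ties: a one-sentence
#' abstract is `last`, and in a two-sentence abstract the second sentence is
#' `last`.
#'
#' @param index_in_zone 0-based sentence index (vectorised).
#' @param n_sentences Number of sentences in the abstract.
#' @return Character vector in `{"first_or_second", "last", "other"}`.
#' @export
abstract_location_class <- function(index_in_zone, n_sentences) {
  vapply(index_in_zone, function(i) {
    if (n_sentences <= 0L || i < 0L || i >= n_sentences) {
      stop("sentence index ", i, " outside abstract of length ", n_sentences)
    }
    if (i == n_sentences - 1L) "last"
    else if (i <= 1L) "first_or_second"
    else "other"
  }, character(1))
}

#' Parse sectioned document records
#'
#' Reads either the JSON-lines dialect (one object per document with keys
#' `doc_id`, `article_type`, `open_access`, `title`, `abstract`,
#' `sections: [{heading, text}]`, `captions: [{kind, text}]`) or the minimal
#' JATS-like XML dialect (`<article article-type=.. open-access=..>` with
#' `article-id`, `title`, `abstract`, `sec/title` + `sec/p`, `fig/caption`,
#' `table-wrap/caption`). Records that fail to parse are skipped and reported
#' in the `problems` attribute rather than aborting the batch.
#'
#' @param path File path, or a character vector of JSON lines / an XML string.
#' @param format `"auto"` (default), `"jsonl"` or `"xml"`.
#' @return List of `td_document`, with attribute `problems` (tibble with
#'   columns `record` and `message`) when any record failed.
#' @export
parse_documents <- function(path, format = c("auto", "jsonl", "xml")) {
  format <- match.arg(format)
  is_file <- length(path) == 1L && !grepl("[{<\n]", path) && file.exists(path)
  content <- if (is_file) readLines(path, encoding = "UTF-8", warn = FALSE) else path
  if (format == "auto") {
    first <- trimws(paste(content, collapse = "\n"))
    format <- if (startsWith(first, "<")) "xml" else if (startsWith(first, "{")) "jsonl"
      else stop("cannot detect dialect: input starts with neither '{' nor '<'")
  }
  if (format == "jsonl") parse_documents_jsonl(content) else parse_documents_xml(content)
}

parse_documents_jsonl <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  docs <- list()
  problems <- tibble::tibble(record = integer(0), message = character(0))
  for (i in seq_along(lines)) {
    doc <- tryCatch({
      rec <- jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE)
      if (is.null(rec$doc_id)) stop("record missing doc_id")
      new_document(
        doc_id = as.character(rec$doc_id),
        article_type = rec$article_type %||% NA_character_,
        title = rec$title %||% "",
        abstract = rec$abstract %||% "",
        sections = rec$sections %||% list(),
        captions = rec$captions %||% list(),
        open_access = isTRUE(rec$open_access)
      )
    }, error = function(e) e)
    if (inherits(doc, "error")) {
      problems <- dplyr::bind_rows(problems, tibble::tibble(
        record = i, message = conditionMessage(doc)
      ))
    } else {
      docs <- c(docs, list(doc))
    }
  }
  if (nrow(problems) > 0L) attr(docs, "problems") <- problems
  docs
}

parse_documents_xml <- function(content) {
  xml <- xml2::read_xml(paste(content, collapse = "\n"))
  articles <- xml2::xml_find_all(xml, "//article")
  if (length(articles) == 0L && xml2::xml_name(xml) == "article") {
    articles <- list(xml)
  }
  docs <- list()
  problems <- tibble::tibble(record = integer(0), message = character(0))
  txt <- function(node, xpath) {
    found <- xml2::xml_find_first(node, xpath)
    if (inherits(found, "xml_missing")) "" else trimws(xml2::xml_text(found))
  }
  for (i in seq_along(articles)) {
    a <- articles[[i]]
    doc <- tryCatch({
      doc_id <- txt(a, "./article-id")
      if (!nzchar(doc_id)) stop("record missing doc_id")
      secs <- lapply(xml2::xml_find_all(a, "./sec"), function(s) {
        list(
          heading = txt(s, "./title"),
          text = paste(trimws(xml2::xml_text(xml2::xml_find_all(s, "./p"))),
                       collapse = " ")
        )
      })
      caps <- c(
        lapply(xml2::xml_find_all(a, "./fig/caption"), function(cn) {
          list(kind = "figure", text = trimws(xml2::xml_text(cn)))
        }),
        lapply(xml2::xml_find_all(a, "./table-wrap/caption"), function(cn) {
          list(kind = "table", text = trimws(xml2::xml_text(cn)))
        })
      )
      new_document(
        doc_id = doc_id,
        article_type = xml2::xml_attr(a, "article-type"),
        title = txt(a, "./title"),
        abstract = txt(a, "./abstract"),
        sections = secs,
        captions = caps,
        open_access = identical(xml2::xml_attr(a, "open-access"), "yes")
      )
    }, error = function(e) e)
    if (inherits(doc, "error")) {
      problems <- dplyr::bind_rows(problems, tibble::tibble(
        record = i, message = conditionMessage(doc)
      ))
    } else {
      docs <- c(docs, list(doc))
    }
  }
  if (nrow(problems) > 0L) attr(docs, "problems") <- problems
  docs
}

#' Serialize documents to the JSON-lines dialect
#'
#' Inverse of [parse_documents()] for the JSON-lines dialect: re-parsing the
#' output yields documents with identical zones and sentences.
#'
#' @param documents List of `td_document`.
#' @param path Optional output file; when `NULL` the lines are returned.
#' @return Character vector of JSON lines (invisibly when written to `path`).
#' @export
write_documents_jsonl <- function(documents, path = NULL) {
  lines <- vapply(documents, function(d) {
    labels <- vapply(d$zones, `[[`, character(1), "label")
    body <- d$zones[!(labels %in% c("title", "abstract", "figure", "table"))]
    caps <- d$zones[labels %in% c("figure", "table")]
    rec <- list(
      doc_id = d$doc_id,
      article_type = d$article_type,
      open_access = d$is_open_access_fulltext,
      title = d$zones[[which(labels == "title")]]$text,
      abstract = d$zones[[which(labels == "abstract")]]$text,
      sections = lapply(body, function(z) {
        list(heading = z$original_heading, text = z$text)
      }),
      captions = lapply(caps, function(z) list(kind = z$label, text = z$text))
    )
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  }, character(1))
  if (!is.null(path)) {
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(lines))
  }
  lines
}
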