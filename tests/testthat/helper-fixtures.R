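# Small lexicons and documents shared across tests.

tiny_target_lexicon <- function(extra = NULL) {
  raw <- tibble::tibble(
    surface = c("IGF1", "NOD2", "insulin-like growth factor 1",
                "growth factor", "TNF alpha"),
    identifier = c("P05019", "Q9HC29", "P05019", "PX001", "P01375")
  )
  if (!is.null(extra)) raw <- dplyr::bind_rows(raw, extra)
  refine_lexicon(raw, "target")
}

tiny_disease_lexicon <- function(extra = NULL) {
  raw <- tibble::tibble(
    surface = c("diabetes", "inflammatory bowel disease", "ALS",
                "amyotrophic lateral sclerosis"),
    identifier = c("EFO_0000400", "EFO_0003767", "EFO_0000253", "EFO_0000253")
  )
  if (!is.null(extra)) raw <- dplyr::bind_rows(raw, extra)
  refine_lexicon(raw, "disease")
}

abstract_doc <- function(doc_id = "PM1", abstract = "", title = "A study",
                         article_type = "research-article") {
  new_document(doc_id, article_type, title = title, abstract = abstract)
}
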