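pair_doc <- function(abstract, doc_id = "PM1", ...) {
  new_document(doc_id, "research-article", title = "A study",
               abstract = abstract, ...)
}

annotate_one <- function(doc) {
  annotate(doc, tiny_target_lexicon(), tiny_disease_lexicon())
}

test_that("one event per sentence per distinct pair, deduplicated", {
  # 1 target + 1 disease -> 1 event
  d1 <- pair_doc("IGF1 is linked to diabetes.")
  e1 <- extract_events(annotate_one(d1), list(d1))
  expect_identical(nrow(e1[e1$zone_label == "abstract", ]), 1L)

  # two targets x one disease -> 2 events
  d2 <- pair_doc("IGF1 and NOD2 are linked to diabetes.")
  e2 <- extract_events(annotate_one(d2), list(d2))
  abs2 <- e2[e2$zone_label == "abstract", ]
  expect_identical(nrow(abs2), 2L)
  expect_setequal(abs2$target_id, c("P05019", "Q9HC29"))

  # repeated mentions of the same pair in one sentence count once
  d3 <- pair_doc("IGF1 and IGF1 again associate with diabetes.")
  e3 <- extract_events(annotate_one(d3), list(d3))
  expect_identical(nrow(e3[e3$zone_label == "abstract", ]), 1L)
})

test_that("abstract events carry their sentence location class", {
  d <- pair_doc(paste(
    "IGF1 is linked to diabetes.",
    "Methods were standard.",
    "IGF1 tracked diabetes severity.",
    "We conclude IGF1 drives diabetes."
  ))
  e <- extract_events(annotate_one(d), list(d))
  abs_e <- e[e$zone_label == "abstract", ]
  expect_identical(
    abs_e$abstract_location_class[order(abs_e$sentence_index)],
    c("first_or_second", "other", "last")
  )
  expect_true(all(is.na(e$abstract_location_class[e$zone_label != "abstract"])))
})

test_that("only research articles survive the type filter", {
  docs <- list(
    new_document("R1", "research-article", title = "t", abstract = "a."),
    new_document("R2", "review", title = "t", abstract = "a."),
    new_document("R3", "case-report", title = "t", abstract = "a."),
    new_document("R4", "Research", title = "t", abstract = "a.")
  )
  kept <- filter_article_type(docs)
  expect_setequal(vapply(kept, `[[`, character(1), "doc_id"), c("R1", "R4"))
  expect_setequal(attr(kept, "removed"), c("R2", "R3"))

  docs_na <- c(docs[1], list(new_document("R5", NA_character_,
                                          title = "t", abstract = "a.")))
  expect_warning(kept_na <- filter_article_type(docs_na), "missing")
  expect_identical(vapply(kept_na, `[[`, character(1), "doc_id"), "R1")
})

test_that("events in excluded sections are removed", {
  d <- new_document("FX", "research-article", title = "t",
                    abstract = "",
                    sections = list(
                      list(heading = "Methods", text = "IGF1 predicts diabetes."),
                      list(heading = "Results", text = "IGF1 predicts diabetes.")
                    ),
                    open_access = TRUE)
  e <- extract_events(annotate_one(d), list(d))
  expect_setequal(unique(e$zone_label), c("methods", "results"))
  f <- filter_excluded_sections(e)
  expect_identical(unique(f$zone_label), "results")
  expect_identical(nrow(filter_excluded_sections(e[0, ])), 0L)
})

test_that("aggregation tallies counts by zone, location and gene mentions", {
  d <- new_document(
    "AG1", "research-article",
    title = "IGF1 and diabetes",
    abstract = "Background here. Also here. IGF1 was assayed. IGF1 predicts diabetes.",
    sections = list(
      list(heading = "Results", text = "IGF1 predicts diabetes. IGF1 tracked diabetes.")
    ),
    open_access = TRUE
  )
  m <- annotate_one(d)
  e <- filter_excluded_sections(extract_events(m, list(d)))
  rec <- aggregate_associations(e, m, list(d))
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$count_title, 1L)
  expect_identical(rec$count_results, 2L)
  expect_identical(rec$count_abs_last, 1L)
  expect_identical(rec$count_abstract, 1L)
  expect_identical(rec$body_total, 2L)
  # mention-level: the gene appears in two abstract sentences
  expect_identical(rec$gene_abstract_mentions, 2L)
  expect_true(rec$is_fulltext)
  # invariant: abstract location counts sum to the abstract zone count
  expect_identical(
    rec$count_abs_first_or_second + rec$count_abs_last + rec$count_abs_other,
    rec$count_abstract
  )
})

test_that("minimum-occurrence rule drops body-once-only associations", {
  rec <- function(body, title, abstract) {
    tibble::tibble(
      doc_id = "X", target_id = "T", disease_id = "D", is_fulltext = TRUE,
      count_title = title, count_abstract = abstract, body_total = body
    )
  }
  expect_identical(nrow(filter_min_occurrence(rec(1L, 0L, 0L))), 0L)
  expect_identical(nrow(filter_min_occurrence(rec(1L, 0L, 1L))), 1L)
  expect_identical(nrow(filter_min_occurrence(rec(2L, 0L, 0L))), 1L)
  expect_identical(nrow(filter_min_occurrence(rec(1L, 1L, 0L))), 1L)
  # abstract-only documents pass untouched
  expect_identical(nrow(filter_min_occurrence(rec(0L, 0L, 2L))), 1L)
})

test_that("each filter is non-increasing on its input", {
  corp <- generate_corpus(corpus_spec(n_abstracts = 4, n_fulltexts = 4,
                                      distractor_rate = 1, seed = 11))
  docs <- corp$documents
  kept_docs <- suppressWarnings(filter_article_type(docs))
  expect_lte(length(kept_docs), length(docs))
  m <- annotate_corpus(kept_docs, corp$target_lexicon, corp$disease_lexicon)
  e <- extract_events(m, kept_docs)
  e2 <- filter_excluded_sections(e)
  expect_lte(nrow(e2), nrow(e))
  r <- aggregate_associations(e2, m, kept_docs)
  r2 <- filter_min_occurrence(r)
  expect_lte(nrow(r2), nrow(r))
})
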