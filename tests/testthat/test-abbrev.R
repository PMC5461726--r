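make_als_doc <- function(abstract, doc_id = "PMD", ...) {
  new_document(doc_id, "research-article", title = "A study",
               abstract = abstract, ...)
}

test_that("parenthesised uppercase short forms become candidates", {
  doc <- make_als_doc(
    "Training from first aid to advanced life support (ALS) is standard."
  )
  m <- annotate(doc, tiny_target_lexicon(), tiny_disease_lexicon())
  cands <- find_candidates(doc, m)
  expect_identical(nrow(cands), 1L)
  expect_identical(cands$short_form, "ALS")
  # N+1 = 4 words immediately before the parenthesis
  expect_identical(cands$long_form, "to advanced life support")
  expect_identical(cands$entity_kind, "disease")
  expect_identical(unlist(cands$identifiers), "EFO_0000253")
})

test_that("length and case requirements exclude non-candidates", {
  doc <- make_als_doc("Some marker (ALSXYZ) and another (p53) appeared near ALS.")
  m <- annotate(doc, tiny_target_lexicon(), tiny_disease_lexicon())
  cands <- find_candidates(doc, m)
  expect_identical(nrow(cands), 0L)
  # property: no candidate is ever long or lowercase-containing
  doc2 <- make_als_doc("We saw ALS (ALS) here (IGF1) and (NOD2) there.")
  m2 <- annotate(doc2, tiny_target_lexicon(), tiny_disease_lexicon())
  cands2 <- find_candidates(doc2, m2)
  expect_true(all(nchar(cands2$short_form) < 6))
  expect_true(all(cands2$short_form == toupper(cands2$short_form)))
})

test_that("disease rule D1 keeps a candidate whose dictionary long form is present", {
  doc <- make_als_doc(paste(
    "Patients had amyotrophic lateral sclerosis at baseline.",
    "Severity of ALS (ALS) was graded."
  ))
  m <- annotate(doc, tiny_target_lexicon(), tiny_disease_lexicon())
  cand <- find_candidates(doc, m)
  dec <- filter_disease_candidate(cand[1, ], doc, tiny_disease_lexicon())
  expect_true(dec$kept)
  expect_identical(dec$rule_fired, "D1")
})

test_that("disease rule D2 keeps keyword-bearing long forms, else drops", {
  lex <- tiny_disease_lexicon(
    tibble::tibble(surface = "ALD", identifier = "EFO_9")
  )
  doc_kw <- make_als_doc("Adrenoleukodystrophy-like syndrome (ALD) was studied.")
  m <- annotate(doc_kw, tiny_target_lexicon(), lex)
  cand <- find_candidates(doc_kw, m)
  dec <- filter_disease_candidate(cand[1, ], doc_kw, lex)
  expect_true(dec$kept)
  expect_identical(dec$rule_fired, "D2")

  doc_fp <- make_als_doc(
    "Training covers advanced life support (ALS) for nurses. ALS uptake grew."
  )
  m2 <- annotate(doc_fp, tiny_target_lexicon(), tiny_disease_lexicon())
  cand2 <- find_candidates(doc_fp, m2)
  dec2 <- filter_disease_candidate(cand2[1, ], doc_fp, tiny_disease_lexicon())
  expect_false(dec2$kept)
  expect_identical(dec2$rule_fired, "none")
})

test_that("gene rule G1 needs >3 body occurrences and open-access full text", {
  tl <- tiny_target_lexicon(tibble::tibble(surface = "XK4", identifier = "QX"))
  body <- paste(rep("The XK4 assay was repeated.", 4), collapse = " ")
  oa <- new_document("OA1", "research-article", title = "t",
                     abstract = "Novel marker (XK4) found.",
                     sections = list(list(heading = "Results", text = body)),
                     open_access = TRUE)
  m <- annotate(oa, tl, tiny_disease_lexicon())
  cand <- find_candidates(oa, m)
  dec <- filter_gene_candidate(cand[1, ], oa, tl, mentions = m)
  expect_true(dec$kept)
  expect_identical(dec$rule_fired, "G1")

  # same text but abstract-only: G1 cannot apply and nothing else fires
  ab <- make_als_doc("Novel marker (XK4) found. The XK4 assay was repeated.")
  m2 <- annotate(ab, tl, tiny_disease_lexicon())
  cand2 <- find_candidates(ab, m2)
  dec2 <- filter_gene_candidate(cand2[1, ], ab, tl, mentions = m2)
  expect_false(dec2$kept)

  # exactly 3 body occurrences is not "more than 3"
  body3 <- paste(rep("The XK4 assay was repeated.", 3), collapse = " ")
  oa3 <- new_document("OA3", "research-article", title = "t",
                      abstract = "Novel marker (XK4) found.",
                      sections = list(list(heading = "Results", text = body3)),
                      open_access = TRUE)
  m3 <- annotate(oa3, tl, tiny_disease_lexicon())
  cand3 <- find_candidates(oa3, m3)
  dec3 <- filter_gene_candidate(cand3[1, ], oa3, tl, mentions = m3)
  expect_false(dec3$kept)
})

test_that("gene rules G2 and G3 inspect the long form", {
  tl <- tiny_target_lexicon(tibble::tibble(
    surface = c("ALP", "IGF1R", "TNF"), identifier = c("Q2", "Q3", "Q4")
  ))
  # G2: long form equals a dictionary/enzyme name
  doc <- make_als_doc("Assays used tumor necrosis factor (TNF) protocols.")
  m <- annotate(doc, tl, tiny_disease_lexicon())
  cand <- find_candidates(doc, m)
  dec <- filter_gene_candidate(cand[1, ], doc, tl,
                               enzyme_terms = "tumor necrosis factor",
                               target_keywords = character(0), mentions = m)
  expect_true(dec$kept)
  expect_identical(dec$rule_fired, "G2")

  # G3 via -ases suffix
  doc2 <- make_als_doc("Activity of alkaline phosphatases (ALP) was high.")
  m2 <- annotate(doc2, tl, tiny_disease_lexicon())
  cand2 <- find_candidates(doc2, m2)
  dec2 <- filter_gene_candidate(cand2[1, ], doc2, tl, mentions = m2)
  expect_true(dec2$kept)
  expect_identical(dec2$rule_fired, "G3")

  # G3 via keyword in the long form
  doc3 <- make_als_doc("The growth factor receptor 1 (IGF1R) was cloned.")
  m3 <- annotate(doc3, tl, tiny_disease_lexicon())
  cand3 <- find_candidates(doc3, m3)
  dec3 <- filter_gene_candidate(cand3[1, ], doc3, tl, mentions = m3)
  expect_true(dec3$kept)
  expect_identical(dec3$rule_fired, "G3")
})

test_that("gene rule G4 counts supporting sentences with the right thresholds", {
  tl <- tiny_target_lexicon(tibble::tibble(surface = "XK4", identifier = "QX"))
  support <- "The XK4 mutation worsens diabetes."
  # abstract-only: one supporting sentence is not enough, two are
  one <- make_als_doc(paste("Marker (XK4) described.", support))
  m1 <- annotate(one, tl, tiny_disease_lexicon())
  d1 <- filter_gene_candidate(find_candidates(one, m1)[1, ], one, tl,
                              mentions = m1)
  expect_false(d1$kept)

  two <- make_als_doc(paste("Marker (XK4) described.", support, support))
  m2 <- annotate(two, tl, tiny_disease_lexicon())
  d2 <- filter_gene_candidate(find_candidates(two, m2)[1, ], two, tl,
                              mentions = m2)
  expect_true(d2$kept)
  expect_identical(d2$rule_fired, "G4")

  # full text: two supporting sentences miss the threshold of three
  ft2 <- new_document("FT2", "research-article", title = "t",
                      abstract = "Marker (XK4) described.",
                      sections = list(list(heading = "Results",
                                           text = paste(support, support))),
                      open_access = TRUE)
  mf <- annotate(ft2, tl, tiny_disease_lexicon())
  df2 <- filter_gene_candidate(find_candidates(ft2, mf)[1, ], ft2, tl,
                               mentions = mf)
  expect_false(df2$kept)

  ft3 <- new_document("FT3", "research-article", title = "t",
                      abstract = "Marker (XK4) described.",
                      sections = list(list(heading = "Results",
                                           text = paste(support, support, support))),
                      open_access = TRUE)
  mf3 <- annotate(ft3, tl, tiny_disease_lexicon())
  df3 <- filter_gene_candidate(find_candidates(ft3, mf3)[1, ], ft3, tl,
                               mentions = mf3)
  expect_true(df3$kept)
  expect_identical(df3$rule_fired, "G4")
})

test_that("dropping a candidate removes every matching mention in the document", {
  doc <- make_als_doc(
    "Training covers advanced life support (ALS). ALS uptake grew. ALS again."
  )
  m <- annotate(doc, tiny_target_lexicon(), tiny_disease_lexicon())
  res <- filter_abbreviations(doc, m, tiny_target_lexicon(),
                              tiny_disease_lexicon())
  expect_false(res$decisions$kept)
  expect_identical(nrow(res$mentions), 0L)
  # never adds mentions; kept/empty decisions leave input untouched
  expect_identical(apply_decisions(m, NULL), m)
  kept_dec <- res$decisions
  kept_dec$kept <- TRUE
  expect_identical(apply_decisions(m, kept_dec), m)
})

test_that("conflicting decisions for one candidate key are rejected", {
  doc <- make_als_doc("Advanced life support (ALS) training.")
  m <- annotate(doc, tiny_target_lexicon(), tiny_disease_lexicon())
  dec <- filter_abbreviations(doc, m, tiny_target_lexicon(),
                              tiny_disease_lexicon())$decisions
  expect_error(apply_decisions(m, dplyr::bind_rows(dec, dec)), "conflicting")
})
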