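record_fixture <- function(..., is_fulltext = TRUE) {
  counts <- list(...)
  row <- list(doc_id = "X", target_id = "T", disease_id = "D",
              is_fulltext = is_fulltext)
  all_cols <- c(
    "count_title", "count_abs_first_or_second", "count_abs_last",
    "count_abs_other",
    paste0("count_", setdiff(zone_labels(), c("title", "abstract"))),
    "count_abstract", "body_total", "gene_abstract_mentions"
  )
  for (col in all_cols) row[[col]] <- 0L
  for (nm in names(counts)) row[[nm]] <- counts[[nm]]
  row$count_abstract <- row$count_abs_first_or_second +
    row$count_abs_last + row$count_abs_other
  tibble::as_tibble(row)
}

test_that("default weights are the published sentence-location and section weights", {
  w <- weight_config()
  expect_identical(
    w$sentence_location_weights,
    c(first_or_second = 2, last = 5, other = 3)
  )
  expect_identical(
    w$section_weights,
    c(title = 10, results = 5, figure = 5, table = 5, discussion = 2,
      conclusion = 2, introduction = 1, case_study = 1, appendix = 1,
      other = 1)
  )
  expect_identical(w$gene_abstract_coefficient, 0.2)
})

test_that("S1 weights abstract locations and adds the gene bonus", {
  expect_equal(
    score_s1(record_fixture(count_abs_last = 1L, gene_abstract_mentions = 1L)),
    5.2
  )
  expect_equal(score_s1(record_fixture()), 0)
  expect_equal(
    score_s1(record_fixture(count_abs_first_or_second = 1L,
                            count_abs_other = 2L,
                            gene_abstract_mentions = 3L)),
    2 + 6 + 0.6
  )
})

test_that("S2 weights sections, title included, abstract excluded", {
  expect_equal(score_s2(record_fixture(count_results = 1L)), 5)
  expect_equal(score_s2(record_fixture(count_introduction = 1L)), 1)
  expect_equal(
    score_s2(record_fixture(count_title = 1L, count_discussion = 2L)), 14
  )
  # abstract counts do not leak into S2
  expect_equal(score_s2(record_fixture(count_abs_last = 3L)), 0)
})

test_that("the boosting-up factor is the batch median with empty fallback 0", {
  expect_equal(boosting_up_factor(5), 5)
  expect_equal(boosting_up_factor(c(1, 5, 14)), 5)
  expect_equal(boosting_up_factor(numeric(0)), 0)
  expect_equal(boosting_up_factor(c(2, 4)), 3)
})

test_that("CS1 scores abstract-only records and rejects full-text ones", {
  r_title <- record_fixture(count_title = 1L, is_fulltext = FALSE)
  expect_equal(score_cs1(r_title, boost = 0)$confidence, 10)

  r_zero <- record_fixture(is_fulltext = FALSE)
  expect_equal(score_cs1(r_zero, boost = 5)$confidence, 5)

  r_last <- record_fixture(count_abs_last = 1L, gene_abstract_mentions = 1L,
                           is_fulltext = FALSE)
  expect_equal(score_cs1(r_last, boost = 5)$confidence, 10.2)
  # CS1 = S1 exactly when no title pair and no boost
  expect_equal(score_cs1(r_last, boost = 0)$confidence,
               score_s1(r_last))

  expect_error(score_cs1(record_fixture(count_title = 1L)), "full-text")
})

test_that("CS2 = S1 + S2 for full-text records and rejects abstract-only ones", {
  expect_equal(score_cs2(record_fixture(count_results = 1L))$confidence, 5)
  expect_equal(
    score_cs2(record_fixture(count_abs_last = 1L, count_results = 1L,
                             gene_abstract_mentions = 1L))$confidence,
    10.2
  )
  expect_equal(score_cs2(record_fixture())$confidence, 0)
  expect_error(score_cs2(record_fixture(is_fulltext = FALSE)), "abstract-only")

  # a single title-only pair scores 10x a single introduction-only pair
  expect_equal(
    score_cs2(record_fixture(count_title = 1L))$confidence,
    10 * score_cs2(record_fixture(count_introduction = 1L))$confidence
  )
})

test_that("confidence is monotone in every count", {
  base <- record_fixture(count_abs_last = 1L, count_results = 2L,
                         gene_abstract_mentions = 1L)
  base_conf <- score_cs2(base)$confidence
  count_cols <- grep("^count_|^gene_abstract", names(base), value = TRUE)
  count_cols <- setdiff(count_cols, c("count_abstract", "body_total",
                                      paste0("count_", excluded_zone_labels())))
  for (col in count_cols) {
    bumped <- base
    bumped[[col]] <- bumped[[col]] + 1L
    bumped$count_abstract <- bumped$count_abs_first_or_second +
      bumped$count_abs_last + bumped$count_abs_other
    expect_gte(score_cs2(bumped)$confidence, base_conf)
  }
})

test_that("ranking is a deterministic total order with doc_id tie-breaks", {
  scores <- tibble::tibble(
    doc_id = c("B", "A", "C"), target_id = "T", disease_id = "D",
    s1 = 0, s2 = 0, boosting_up_factor = 0,
    confidence = c(5, 5, 10.2), formula_used = "CS2"
  )
  ranked <- rank_documents(scores, "T", "D")
  expect_identical(ranked$doc_id, c("C", "A", "B"))
  # permutation invariance
  ranked2 <- rank_documents(scores[c(3, 1, 2), ], "T", "D")
  expect_identical(ranked2, ranked)
  expect_identical(nrow(rank_documents(scores, "T", "ZZZ")), 0L)
})

test_that("batch scoring uses the full-text median as the abstract boost", {
  recs <- dplyr::bind_rows(
    record_fixture(count_results = 1L),                       # S2 = 5
    record_fixture(count_introduction = 1L),                  # S2 = 1
    record_fixture(count_title = 1L, count_discussion = 2L),  # S2 = 14
    record_fixture(count_abs_last = 1L, is_fulltext = FALSE)
  )
  recs$doc_id <- c("F1", "F2", "F3", "A1")
  scored <- score_documents(recs)
  expect_equal(attr(scored, "boosting_up_factor"), 5)
  a1 <- scored[scored$doc_id == "A1", ]
  expect_identical(a1$formula_used, "CS1")
  expect_equal(a1$confidence, 5 + 5)  # S1 last-sentence + boost
})
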