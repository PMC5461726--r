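#' Specify a synthetic corpus
#'
#' Describes a deterministic corpus of template-based documents with planted
#' target-disease associations, used to test every pipeline stage without
#' external data. Sentences are generated from fixed templates ("TGX1 is
#' associated with morbidity type 2 ...") so sentence splitting and matching
#' are unambiguous and the expected association record of every planted
#' plan is known by construction.
#'
#' @param n_abstracts,n_fulltexts Number of abstract-only and full-text
#'   documents carrying planted associations. Ignored for documents given
#'   explicitly via `planted`.
#' @param planted Optional list of plans. Each plan is a list with elements
#'   `target` and `disease` (positive integer indices into the generated
#'   lexicons), and optionally `title` (0/1 co-occurrence in the title),
#'   `abstract` (named counts among `first_or_second`, `last`, `other`),
#'   `body` (named counts per body zone label, e.g. `c(results = 2)`),
#'   `gene_extra_abstract` (additional gene-only abstract sentences),
#'   `article_type` (default `"research-article"`). A plan with any `body`
#'   or `title` count becomes an open-access full-text document. When
#'   `planted` is `NULL`, plans are drawn deterministically from the seed.
#' @param distractor_rate Number of distractor documents per planted
#'   document (rounded to a count). Distractors cycle through: a review
#'   article with a co-occurrence (removed by the article-type filter), a
#'   research article whose only co-occurrence sits in Methods (removed by
#'   the section filter), and a full text with a single body co-occurrence
#'   (removed by the minimum-occurrence filter).
#' @param ambiguous_abbrevs List of `list(short_form =, long_form =)` pairs:
#'   each generates an abstract whose short form is annotated as a disease
#'   but glossed by a misleading long form, exercising the abbreviation
#'   filter.
#' @param seed Integer seed; a fixed seed yields a byte-identical corpus.
#' @return A `td_corpus_spec`.
#' @export
corpus_spec <- function(n_abstracts = 5L, n_fulltexts = 5L, planted = NULL,
                        distractor_rate = 0, ambiguous_abbrevs = list(),
                        seed = 1L) {
  stopifnot(n_abstracts >= 0L, n_fulltexts >= 0L, distractor_rate >= 0)
  structure(
    list(n_abstracts = as.integer(n_abstracts),
         n_fulltexts = as.integer(n_fulltexts),
         planted = planted, distractor_rate = distractor_rate,
         ambiguous_abbrevs = ambiguous_abbrevs, seed = as.integer(seed)),
    class = "td_corpus_spec"
  )
}

# run code with a private RNG stream, restoring the caller's state
with_corpus_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

target_surface <- function(i) sprintf("TGX%d", i)
target_identifier <- function(i) sprintf("T%04d", i)
disease_surface <- function(i) sprintf("morbidity type %d", i)
disease_identifier <- function(i) sprintf("D%04d", i)

cooc_sentence <- function(g, d) {
  sprintf("%s is associated with %s in this cohort.", g, d)
}
gene_sentence <- function(g) {
  sprintf("Serum levels of %s were measured at baseline.", g)
}
filler_sentence <- function() {
  "The study cohort was recruited prospectively."
}

body_zone_heading <- function(zone) {
  c(introduction = "Introduction", methods = "Methods", results = "Results",
    discussion = "Discussion", conclusion = "Conclusion",
    case_study = "Case Study", appendix = "Appendix",
    references = "References", acknowledgement_funding = "Acknowledgements",
    competing_interests = "Competing Interests",
    author_contribution = "Author Contributions",
    supplementary = "Supplementary Material", other = "Miscellany")[[zone]]
}

normalise_plan <- function(plan, doc_id) {
  zones_known <- setdiff(zone_labels(), c("title", "abstract"))
  body <- plan$body %||% integer(0)
  if (length(body) > 0L && !all(names(body) %in% zones_known)) {
    stop("plan for ", doc_id, " references unknown zone(s): ",
         paste(setdiff(names(body), zones_known), collapse = ", "))
  }
  abs_counts <- c(first_or_second = 0L, last = 0L, other = 0L)
  if (!is.null(plan$abstract)) {
    if (!all(names(plan$abstract) %in% names(abs_counts))) {
      stop("plan for ", doc_id, " has unknown abstract location(s): ",
           paste(setdiff(names(plan$abstract), names(abs_counts)),
                 collapse = ", "))
    }
    abs_counts[names(plan$abstract)] <- as.integer(plan$abstract)
    if (abs_counts[["first_or_second"]] > 2L) {
      stop("at most 2 first_or_second co-occurrences fit an abstract")
    }
    if (abs_counts[["last"]] > 1L) stop("at most 1 last-sentence co-occurrence")
  }
  list(
    target = plan$target, disease = plan$disease,
    title = as.integer(plan$title %||% 0L),
    abstract = abs_counts,
    body = body,
    gene_extra_abstract = as.integer(plan$gene_extra_abstract %||% 0L),
    article_type = plan$article_type %||% "research-article",
    doc_id = doc_id
  )
}

build_planned_document <- function(plan) {
  g <- target_surface(plan$target)
  d <- disease_surface(plan$disease)
  title <- if (plan$title >= 1L) {
    sprintf("%s and its role in %s", g, d)
  } else {
    "A prospective biomarker study"
  }
  # abstract layout: [slot0, slot1] first_or_second, middle block "other",
  # final sentence "last"; always >= 4 sentences so classes are stable
  f <- plan$abstract[["first_or_second"]]
  o <- plan$abstract[["other"]]
  l <- plan$abstract[["last"]]
  sents <- c(
    if (f >= 1L) cooc_sentence(g, d) else filler_sentence(),
    if (f >= 2L) cooc_sentence(g, d) else filler_sentence(),
    rep(cooc_sentence(g, d), o),
    rep(gene_sentence(g), plan$gene_extra_abstract),
    filler_sentence(),
    if (l >= 1L) cooc_sentence(g, d) else filler_sentence()
  )
  abstract <- paste(sents, collapse = " ")

  body <- plan$body
  sections <- list()
  captions <- list()
  for (zone in names(body)) {
    text <- paste(c(rep(cooc_sentence(g, d), body[[zone]]),
                    filler_sentence()), collapse = " ")
    if (zone %in% c("figure", "table")) {
      captions <- c(captions, list(list(kind = zone, text = text)))
    } else {
      sections <- c(sections, list(list(heading = body_zone_heading(zone),
                                        text = text)))
    }
  }
  is_fulltext <- length(body) > 0L || plan$title >= 1L
  if (is_fulltext && length(sections) == 0L && length(captions) == 0L) {
    sections <- list(list(heading = "Results", text = filler_sentence()))
  }
  new_document(
    doc_id = plan$doc_id, article_type = plan$article_type,
    title = title, abstract = abstract,
    sections = sections, captions = captions,
    open_access = is_fulltext
  )
}

# expected post-filter association record for a plan, or NULL if the
# pipeline's document-level filters remove it
expected_record <- function(plan) {
  if (!plan$article_type %in% c("research-article", "Research")) return(NULL)
  body <- plan$body
  body <- body[!(names(body) %in% excluded_zone_labels())]
  body_total <- sum(body)
  n_abs <- sum(plan$abstract)
  if (body_total == 1L && plan$title == 0L && n_abs == 0L) return(NULL)
  if (body_total == 0L && plan$title == 0L && n_abs == 0L) return(NULL)

  rec <- empty_records()[0, ]
  row <- stats::setNames(
    as.list(rep(0L, length(association_count_columns()))),
    association_count_columns()
  )
  row$doc_id <- plan$doc_id
  row$target_id <- target_identifier(plan$target)
  row$disease_id <- disease_identifier(plan$disease)
  row$is_fulltext <- length(plan$body) > 0L || plan$title >= 1L
  row$count_title <- plan$title
  row$count_abs_first_or_second <- plan$abstract[["first_or_second"]]
  row$count_abs_last <- plan$abstract[["last"]]
  row$count_abs_other <- plan$abstract[["other"]]
  for (zone in names(body)) row[[paste0("count_", zone)]] <- as.integer(body[[zone]])
  row$count_abstract <- as.integer(n_abs)
  row$body_total <- as.integer(body_total)
  # every co-occurrence sentence in the abstract carries one gene mention
  row$gene_abstract_mentions <- as.integer(n_abs + plan$gene_extra_abstract)
  dplyr::bind_rows(rec, tibble::as_tibble(row[names(empty_records())]))
}

random_plans <- function(n_abstracts, n_fulltexts, n_pairs) {
  plans <- list()
  for (i in seq_len(n_abstracts)) {
    plans[[length(plans) + 1L]] <- list(
      target = sample.int(n_pairs, 1L), disease = sample.int(n_pairs, 1L),
      abstract = c(first_or_second = sample(0:2, 1L),
                   last = sample(0:1, 1L), other = sample(0:2, 1L)),
      gene_extra_abstract = sample(0:2, 1L)
    )
  }
  body_zones <- c("introduction", "results", "discussion", "conclusion",
                  "figure", "table", "case_study", "appendix", "other")
  for (i in seq_len(n_fulltexts)) {
    zones <- sample(body_zones, sample(1:3, 1L))
    plans[[length(plans) + 1L]] <- list(
      target = sample.int(n_pairs, 1L), disease = sample.int(n_pairs, 1L),
      title = sample(0:1, 1L),
      abstract = c(first_or_second = sample(0:1, 1L),
                   last = sample(0:1, 1L), other = 0L),
      body = stats::setNames(sample(1:3, length(zones), replace = TRUE), zones),
      gene_extra_abstract = sample(0:1, 1L)
    )
  }
  plans
}

distractor_plan <- function(kind, pair_index, n_pairs) {
  base <- list(target = pair_index, disease = pair_index)
  switch(kind,
    review = c(base, list(article_type = "review",
                          body = c(results = 2L),
                          abstract = c(last = 1L))),
    methods_only = c(base, list(body = c(methods = 2L))),
    body_once = c(base, list(body = c(discussion = 1L)))
  )
}

ambiguous_document <- function(doc_id, short_form, long_form) {
  abstract <- paste(
    filler_sentence(),
    sprintf("Training ranges from basic first aid to %s (%s).",
            long_form, short_form),
    sprintf("Uptake of %s courses has grown steadily.", short_form),
    filler_sentence()
  )
  new_document(doc_id = doc_id, article_type = "research-article",
               title = "An educational survey", abstract = abstract)
}

#' Generate a synthetic corpus with planted associations
#'
#' Builds documents, refined target/disease lexicons, the ground-truth
#' association records each planted plan should yield after all pipeline
#' filters, and relevance judgments (planted documents are relevant for
#' their pair; distractor and ambiguous-abbreviation documents are not).
#' Deterministic in `spec$seed`.
#'
#' @param spec A `td_corpus_spec`.
#' @return List with `documents` (list of `td_document`), `target_lexicon`,
#'   `disease_lexicon` (`td_lexicon`), `ground_truth` (record tibble, see
#'   [aggregate_associations()]), `judgments` (tibble with columns
#'   `association`, `target_id`, `disease_id`, `doc_id`, `relevant`) and
#'   `spec`.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "td_corpus_spec"))
  with_corpus_seed(spec$seed, {
    n_pairs <- 6L
    plans <- spec$planted
    if (is.null(plans)) {
      plans <- random_plans(spec$n_abstracts, spec$n_fulltexts, n_pairs)
    }
    n_pairs <- max(c(n_pairs, vapply(plans, `[[`, numeric(1), "target"),
                     vapply(plans, `[[`, numeric(1), "disease")))
    plans <- lapply(seq_along(plans), function(i) {
      normalise_plan(plans[[i]], sprintf("SYN%04d", i))
    })

    # distractors reuse pair indices so they compete in the same rankings
    n_distract <- round(spec$distractor_rate * length(plans))
    kinds <- c("review", "methods_only", "body_once")
    dplans <- lapply(seq_len(n_distract), function(i) {
      pair <- if (length(plans) > 0L) plans[[1 + (i - 1) %% length(plans)]] else
        list(target = 1L, disease = 1L)
      normalise_plan(
        distractor_plan(kinds[1 + (i - 1) %% 3L], pair$target, n_pairs),
        sprintf("DIS%04d", i)
      )
    })
    # a distractor must target the same disease as its source plan to land
    # in the same ranking
    for (i in seq_along(dplans)) {
      src <- plans[[1 + (i - 1) %% length(plans)]]
      dplans[[i]]$target <- src$target
      dplans[[i]]$disease <- src$disease
    }

    documents <- c(lapply(plans, build_planned_document),
                   lapply(dplans, build_planned_document))
    for (i in seq_along(spec$ambiguous_abbrevs)) {
      ab <- spec$ambiguous_abbrevs[[i]]
      documents <- c(documents, list(ambiguous_document(
        sprintf("AMB%04d", i), ab$short_form, ab$long_form
      )))
    }

    # raw lexicons include a too-short term, a stoplisted term and a Greek
    # variant source so refinement is exercised on every run
    raw_targets <- tibble::tibble(
      surface = c(vapply(seq_len(n_pairs), target_surface, character(1)),
                  "A", "Large", "TNF alpha"),
      identifier = c(vapply(seq_len(n_pairs), target_identifier, character(1)),
                     "T9001", "T9002", "T9003")
    )
    raw_diseases <- tibble::tibble(
      surface = vapply(seq_len(n_pairs), disease_surface, character(1)),
      identifier = vapply(seq_len(n_pairs), disease_identifier, character(1))
    )
    for (i in seq_along(spec$ambiguous_abbrevs)) {
      ab <- spec$ambiguous_abbrevs[[i]]
      id <- sprintf("D9%03d", i)
      raw_diseases <- dplyr::bind_rows(raw_diseases, tibble::tibble(
        surface = c(ab$short_form,
                    sprintf("chronic %s spectrum syndrome", tolower(ab$short_form))),
        identifier = id
      ))
    }
    target_lexicon <- refine_lexicon(raw_targets, "target", stoplist = "large")
    disease_lexicon <- refine_lexicon(raw_diseases, "disease")

    expected <- lapply(plans, expected_record)
    surviving <- plans[!vapply(expected, is.null, logical(1))]
    ground_truth <- dplyr::bind_rows(expected)
    if (nrow(ground_truth) == 0L) ground_truth <- empty_records()
    ground_truth <- dplyr::arrange(ground_truth, .data$doc_id,
                                   .data$target_id, .data$disease_id)

    judgments <- dplyr::bind_rows(
      purrr::map_dfr(surviving, function(p) tibble::tibble(
        target_id = target_identifier(p$target),
        disease_id = disease_identifier(p$disease),
        doc_id = p$doc_id, relevant = TRUE
      )),
      purrr::map_dfr(dplans, function(p) tibble::tibble(
        target_id = target_identifier(p$target),
        disease_id = disease_identifier(p$disease),
        doc_id = p$doc_id, relevant = FALSE
      ))
    )
    if (nrow(judgments) > 0L) {
      judgments$association <- paste(judgments$target_id,
                                     judgments$disease_id, sep = "|")
      judgments <- judgments[, c("association", "target_id", "disease_id",
                                 "doc_id", "relevant")]
    }

    list(documents = documents, target_lexicon = target_lexicon,
         disease_lexicon = disease_lexicon, ground_truth = ground_truth,
         judgments = judgments, spec = spec)
  })
}
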