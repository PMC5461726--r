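#' Average precision of one ranking
#'
#' `AP = (sum over relevant ranks r <= cutoff of precision@r) / R`, where
#' `R` is the number of relevant documents found within the cutoff; 0 when
#' no relevant document appears in the top `cutoff`. Documents ranked
#' higher therefore contribute more.
#'
#' @param ranked Character vector of document ids, best first.
#' @param relevant Character vector of relevant document ids.
#' @param cutoff Evaluation depth (default 25, i.e. the top 25 documents).
#' @return Scalar in `[0, 1]`.
#' @export
#' @examples
#' average_precision(c("a", "b", "c"), relevant = c("a", "c"), cutoff = 3)
average_precision <- function(ranked, relevant, cutoff = 25L) {
  stopifnot(cutoff >= 1L)
  top <- utils::head(ranked, cutoff)
  hits <- top %in% relevant
  if (!any(hits)) return(0)
  prec_at <- cumsum(hits) / seq_along(hits)
  sum(prec_at[hits]) / sum(hits)
}

#' Mean average precision over associations
#'
#' @param rankings Named list: one ranked character vector of doc ids per
#'   association (name = association key).
#' @param judgments Tibble with columns `association`, `doc_id`, `relevant`
#'   (logical); one judgment per (association, doc).
#' @param cutoff Evaluation depth (default 25).
#' @return List with `per_association_ap` (named numeric), `map_value`
#'   (their mean) and `cutoff`.
#' @export
mean_average_precision <- function(rankings, judgments, cutoff = 25L) {
  if (length(rankings) == 0L) stop("no rankings to evaluate")
  ap <- vapply(names(rankings), function(key) {
    rel <- judgments$doc_id[judgments$association == key & judgments$relevant]
    average_precision(rankings[[key]], rel, cutoff)
  }, numeric(1))
  list(per_association_ap = ap, map_value = mean(ap), cutoff = cutoff)
}

#' Pearson correlation between two document score sets
#'
#' Correlates scores over the shared document ids, e.g. abstract-only
#' versus full-text confidence scores for the same articles.
#'
#' @param scores_a,scores_b Named numeric vectors (names = doc ids).
#' @return Pearson correlation coefficient.
#' @export
score_correlation <- function(scores_a, scores_b) {
  shared <- intersect(names(scores_a), names(scores_b))
  if (length(shared) < 2L) {
    stop("need at least 2 shared documents, got ", length(shared))
  }
  a <- scores_a[shared]
  b <- scores_b[shared]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero variance in one of the score sets")
  }
  stats::cor(a, b, method = "pearson")
}
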