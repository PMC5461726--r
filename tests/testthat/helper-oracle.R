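# Independent oracles. These re-derive expected results from first
# principles (substring enumeration, mention walking) without calling the
# implementation paths they check.

# Brute-force dictionary matcher: tests every substring of the sentence
# against the lexicon, keeps word-boundary hits, then greedy left-to-right
# longest-match resolution.
oracle_annotate_sentence <- function(sentence, entries) {
  n <- nchar(sentence)
  word_char <- function(ch) grepl("[[:alnum:]α-ωΑ-Ω]", ch)
  boundary_ok <- function(s, e) {
    pre <- if (s > 1) substr(sentence, s - 1, s - 1) else ""
    pre2 <- if (s > 2) substr(sentence, s - 2, s - 2) else ""
    post <- if (e < n) substr(sentence, e + 1, e + 1) else ""
    post2 <- if (e + 1 < n) substr(sentence, e + 2, e + 2) else ""
    ok_pre <- !word_char(pre) && !(pre == "-" && word_char(pre2))
    ok_post <- !word_char(post) && !(post == "-" && word_char(post2))
    ok_pre && ok_post
  }
  cs <- function(surf) {
    nchar(surf) <= 5 && surf == toupper(surf) && grepl("[A-Z]", surf)
  }
  hits <- NULL
  for (s in seq_len(n)) {
    for (e in s:n) {
      sub <- substr(sentence, s, e)
      for (surf in unique(entries$surface)) {
        match <- if (cs(surf)) identical(sub, surf) else
          identical(tolower(sub), tolower(surf))
        if (match && boundary_ok(s, e)) {
          hits <- rbind(hits, data.frame(start = s, end = e, surface = surf))
        }
      }
    }
  }
  if (is.null(hits)) return(NULL)
  hits <- hits[order(hits$start, -hits$end), , drop = FALSE]
  kept <- NULL
  last_end <- 0
  for (i in seq_len(nrow(hits))) {
    if (hits$start[i] > last_end) {
      kept <- rbind(kept, hits[i, ])
      last_end <- hits$end[i]
    }
  }
  kept
}

oracle_annotate <- function(document, target_lexicon, disease_lexicon) {
  out <- NULL
  for (zone in document$zones) {
    for (si in seq_len(nrow(zone$sentences))) {
      sentence <- zone$sentences$text[si]
      for (kind in c("target", "disease")) {
        entries <- if (kind == "target") target_lexicon$entries else
          disease_lexicon$entries
        hits <- oracle_annotate_sentence(sentence, entries)
        if (is.null(hits)) next
        for (i in seq_len(nrow(hits))) {
          ids <- unique(entries$identifier[entries$surface == hits$surface[i]])
          for (id in ids) {
            out <- rbind(out, data.frame(
              doc_id = document$doc_id, zone_label = zone$label,
              sentence_index = zone$sentences$index_in_zone[si],
              start = hits$start[i] - 1L, end = hits$end[i],
              entity_kind = kind, identifier = id,
              surface = substr(sentence, hits$start[i], hits$end[i]),
              stringsAsFactors = FALSE
            ))
          }
        }
      }
    }
  }
  out
}

# Mention-walking score oracle: recomputes the confidence of every
# (document, target, disease) triple directly from the raw mention list,
# sentence by sentence, weight by weight. Excluded zones contribute 0.
oracle_scores <- function(document, mentions, weights = weight_config(),
                          boost = 0) {
  excluded <- c("methods", "references", "acknowledgement_funding",
                "competing_interests", "author_contribution", "supplementary")
  m <- mentions[mentions$doc_id == document$doc_id, , drop = FALSE]
  labels <- vapply(document$zones, `[[`, character(1), "label")
  n_abs <- nrow(document$zones[[which(labels == "abstract")]]$sentences)
  acc <- list()
  add <- function(tid, did, w) {
    key <- paste(tid, did, sep = "|")
    prev <- if (is.null(acc[[key]])) 0 else acc[[key]]
    acc[[key]] <<- prev + w
  }
  for (zone in document$zones) {
    if (zone$label %in% excluded) next
    for (si in zone$sentences$index_in_zone) {
      here <- m[m$zone_label == zone$label & m$sentence_index == si, ]
      tids <- unique(here$identifier[here$entity_kind == "target"])
      dids <- unique(here$identifier[here$entity_kind == "disease"])
      if (length(tids) == 0 || length(dids) == 0) next
      w <- if (zone$label == "abstract") {
        cls <- if (si == n_abs - 1) "last" else if (si <= 1) "first_or_second"
          else "other"
        weights$sentence_location_weights[[cls]]
      } else {
        weights$section_weights[[zone$label]]
      }
      for (tid in tids) for (did in dids) add(tid, did, w)
    }
  }
  if (length(acc) == 0) return(NULL)
  out <- data.frame(key = names(acc), score = unlist(acc),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$target_id <- sub("\\|.*", "", out$key)
  out$disease_id <- sub(".*\\|", "", out$key)
  # gene-in-abstract bonus for every pair involving that target
  gene_abs <- m[m$entity_kind == "target" & m$zone_label == "abstract", ]
  for (i in seq_len(nrow(out))) {
    g <- sum(gene_abs$identifier == out$target_id[i])
    out$score[i] <- out$score[i] + weights$gene_abstract_coefficient * g
    if (!document$is_open_access_fulltext) out$score[i] <- out$score[i] + boost
  }
  out$doc_id <- document$doc_id
  out[, c("doc_id", "target_id", "disease_id", "score")]
}
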