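#' Default Greek-letter map
#'
#' Bidirectional whole-word mapping between spelled-out Greek letter names
#' (alpha through omega, lower case) and their lower-case symbols. Used to
#' generate dictionary term variants such as `"TNF alpha"` -> `"TNF α"`.
#'
#' @return Named character vector; names are the tokens to replace, values
#'   the replacements. Contains both directions (name -> symbol and
#'   symbol -> name).
#' @export
#' @examples
#' default_greek_map()[["alpha"]]
default_greek_map <- function() {
  names_ <- c(
    "alpha", "beta", "gamma", "delta", "epsilon", "zeta", "eta", "theta",
    "iota", "kappa", "lambda", "mu", "nu", "xi", "omicron", "pi", "rho",
    "sigma", "tau", "upsilon", "phi", "chi", "psi", "omega"
  )
  symbols <- c(
    "α", "β", "γ", "δ", "ε", "ζ", "η",
    "θ", "ι", "κ", "λ", "μ", "ν", "ξ",
    "ο", "π", "ρ", "σ", "τ", "υ", "φ",
    "χ", "ψ", "ω"
  )
  stats::setNames(c(symbols, names_), c(names_, symbols))
}

# Whole-word regex for one Greek token: not flanked by letters or digits.
greek_token_regex <- function(token) {
  stringr::regex(paste0(
    "(?<![\\p{L}\\p{N}])", stringr::str_escape(token), "(?![\\p{L}\\p{N}])"
  ))
}

#' Generate Greek-letter variants of a dictionary surface
#'
#' For each whole-word occurrence of a mappable Greek token (a spelled name
#' like `"alpha"` or a symbol like `"α"`), emits the surface with that
#' occurrence substituted; when several occurrences are present the variant
#' with all of them substituted is emitted as well. The input surface itself
#' is never returned.
#'
#' @param surface Non-empty character scalar.
#' @param greek_map Named character vector as [default_greek_map()].
#' @return Character vector of variant surfaces (possibly empty), deduplicated.
#' @export
#' @examples
#' generate_greek_variants("TNF alpha")
#' generate_greek_variants("BRCA1")
generate_greek_variants <- function(surface, greek_map = default_greek_map()) {
  stopifnot(is.character(surface), length(surface) == 1L, nzchar(surface))
  present <- names(greek_map)[vapply(
    names(greek_map),
    function(tok) stringr::str_detect(surface, greek_token_regex(tok)),
    logical(1)
  )]
  if (length(present) == 0L) return(character(0))

  variants <- character(0)
  for (tok in present) {
    pat <- greek_token_regex(tok)
    locs <- stringr::str_locate_all(surface, pat)[[1]]
    # each single occurrence substituted
    for (i in seq_len(nrow(locs))) {
      v <- paste0(
        substr(surface, 1L, locs[i, "start"] - 1L),
        greek_map[[tok]],
        substr(surface, locs[i, "end"] + 1L, nchar(surface))
      )
      variants <- c(variants, v)
    }
  }
  # all mappable tokens substituted at once
  all_sub <- surface
  for (tok in present) {
    all_sub <- stringr::str_replace_all(all_sub, greek_token_regex(tok), greek_map[[tok]])
  }
  variants <- unique(c(variants, all_sub))
  setdiff(variants, surface)
}

#' Refine a raw term list into a matching lexicon
#'
#' Applies the dictionary refinement used before text mining: terms shorter
#' than three characters are removed (single letters such as "A" are gene
#' names but near-useless as match surfaces), terms ambiguous with common
#' English words (e.g. the protein name "Large") are removed via a
#' case-insensitive stoplist, and Greek-letter variants are generated for the
#' survivors. Variants inherit both filters.
#'
#' @param raw_terms Data frame (or tibble) with columns `surface` and
#'   `identifier`, one row per raw dictionary term.
#' @param entity_kind `"target"` or `"disease"`.
#' @param stoplist Character vector of common words to exclude
#'   (case-insensitive). The exact list is deployment-specific; pass it
#'   explicitly.
#' @param greek_map Named character vector as [default_greek_map()].
#' @param min_nchar Minimum surface length in Unicode characters (default 3).
#' @return A `td_lexicon`: list with `entity_kind`, `entries` (tibble with
#'   columns `surface`, `identifier`, `entity_kind`, `variant_of`, `source`)
#'   and `removed` (tibble with columns `surface`, `identifier`, `rule`
#'   logging every removal).
#' @export
#' @examples
#' raw <- tibble::tibble(
#'   surface = c("A", "Large", "BRCA1", "TNF alpha"),
#'   identifier = c("P_A", "O95237", "P38398", "P01375")
#' )
#' lex <- refine_lexicon(raw, "target", stoplist = "large")
#' lex$entries$surface
refine_lexicon <- function(raw_terms, entity_kind = c("target", "disease"),
                           stoplist = character(0),
                           greek_map = default_greek_map(),
                           min_nchar = 3L) {
  entity_kind <- match.arg(entity_kind)
  raw_terms <- tibble::as_tibble(raw_terms)
  if (nrow(raw_terms) == 0L) {
    stop("`raw_terms` is empty: a lexicon needs at least one term")
  }
  if (!all(c("surface", "identifier") %in% names(raw_terms))) {
    stop("`raw_terms` must have columns `surface` and `identifier`")
  }
  bad <- which(
    is.na(raw_terms$surface) | is.na(raw_terms$identifier) |
      !nzchar(trimws(raw_terms$surface)) | !nzchar(trimws(raw_terms$identifier))
  )
  if (length(bad) > 0L) {
    stop("malformed term row(s): ", paste(bad, collapse = ", "),
         " (empty or missing surface/identifier)")
  }

  stop_lc <- tolower(stoplist)
  classify <- function(surface) {
    if (stringr::str_length(surface) < min_nchar) "length" else
      if (tolower(surface) %in% stop_lc) "stoplist" else NA_character_
  }

  rule <- vapply(raw_terms$surface, classify, character(1), USE.NAMES = FALSE)
  removed <- tibble::tibble(
    surface = raw_terms$surface[!is.na(rule)],
    identifier = raw_terms$identifier[!is.na(rule)],
    rule = rule[!is.na(rule)]
  )
  kept <- raw_terms[is.na(rule), , drop = FALSE]

  entries <- tibble::tibble(
    surface = kept$surface,
    identifier = kept$identifier,
    entity_kind = entity_kind,
    variant_of = NA_character_,
    source = "raw"
  )

  # Greek variants for survivors; variants pass through the same filters.
  var_rows <- purrr::map2_dfr(kept$surface, kept$identifier, function(s, id) {
    vs <- generate_greek_variants(s, greek_map)
    if (length(vs) == 0L) return(NULL)
    tibble::tibble(surface = vs, identifier = id, variant_of = s)
  })
  if (nrow(var_rows) > 0L) {
    vrule <- vapply(var_rows$surface, classify, character(1), USE.NAMES = FALSE)
    removed <- dplyr::bind_rows(removed, tibble::tibble(
      surface = var_rows$surface[!is.na(vrule)],
      identifier = var_rows$identifier[!is.na(vrule)],
      rule = vrule[!is.na(vrule)]
    ))
    var_rows <- var_rows[is.na(vrule), , drop = FALSE]
    entries <- dplyr::bind_rows(entries, tibble::tibble(
      surface = var_rows$surface,
      identifier = var_rows$identifier,
      entity_kind = entity_kind,
      variant_of = var_rows$variant_of,
      source = "greek_variant"
    ))
  }

  entries <- dplyr::distinct(entries, .data$surface, .data$identifier,
                             .keep_all = TRUE)
  structure(
    list(entity_kind = entity_kind, entries = entries, removed = removed),
    class = "td_lexicon"
  )
}

#' @export
print.td_lexicon <- function(x, ...) {
  cat(sprintf(
    "<td_lexicon> kind=%s, %d entries (%d variants), %d removed\n",
    x$entity_kind, nrow(x$entries),
    sum(x$entries$source == "greek_variant"), nrow(x$removed)
  ))
  invisible(x)
}

#' Read a raw term list from a two-column TSV
#'
#' @param path TSV file, UTF-8, columns surface TAB identifier.
#' @param header Whether the first row is a header (default `FALSE`).
#' @return Tibble with columns `surface` and `identifier`.
#' @export
read_term_tsv <- function(path, header = FALSE) {
  df <- utils::read.delim(
    path, header = header, sep = "\t", quote = "",
    colClasses = "character", fileEncoding = "UTF-8",
    col.names = if (header) NULL else c("surface", "identifier")
  )
  if (ncol(df) < 2L) stop("expected two tab-separated columns in ", path)
  names(df)[1:2] <- c("surface", "identifier")
  tibble::as_tibble(df[, 1:2])
}

#' Write a refined lexicon (and its removal log) as TSV
#'
#' @param lexicon A `td_lexicon`.
#' @param path Output TSV for retained entries (surface, identifier).
#' @param removed_path Optional TSV path for the removal log (surface, rule).
#' @return `path`, invisibly.
#' @export
write_lexicon_tsv <- function(lexicon, path, removed_path = NULL) {
  stopifnot(inherits(lexicon, "td_lexicon"))
  utils::write.table(
    lexicon$entries[, c("surface", "identifier")], path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE,
    fileEncoding = "UTF-8"
  )
  if (!is.null(removed_path)) {
    utils::write.table(
      lexicon$removed[, c("surface", "rule")], removed_path,
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE,
      fileEncoding = "UTF-8"
    )
  }
  invisible(path)
}
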