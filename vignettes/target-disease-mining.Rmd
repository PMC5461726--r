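---
title: "Mining and scoring target-disease associations: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and scoring target-disease associations: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdmine)
```

This vignette documents the method implemented by `tdmine`, the choices
behind every tunable, and what the synthetic-corpus tests do and do not
demonstrate about behaviour on real literature.

## The procedure

The pipeline turns a batch of sectioned documents and two refined
dictionaries into scored `(document, target, disease)` evidence records, in
a fixed stage order:

1. **Article-type filter.** Only research articles enter; reviews and case
   reports mostly restate known associations. The research-type set defaults
   to `{"research-article", "Research"}` and is configurable; documents with
   a missing type are dropped with a warning, which matches the filter's
   conservative intent.
2. **Dictionary annotation.** Longest-match, left-to-right, word-boundary
   anchored matching of target and disease surfaces over sentence-split
   zones.
3. **Abbreviation filter.** Rule-based screening of short-form/long-form
   pairs to remove false-positive abbreviation mentions.
4. **Sentence-level co-occurrence extraction.** One event per sentence per
   distinct identifier pair; mention multiplicity inside one sentence does
   not multiply events (the signal is "this sentence relates the pair", not
   how often it names each side).
5. **Section filter.** Events in Methods, References, Acknowledgement &
   Funding, Competing Interests, Author Contribution and Supplementary
   Material are discarded: these zones name genes and diseases for reasons
   (reagents, citations, grants) unrelated to the paper's findings.
6. **Aggregation and minimum-occurrence filter.** Events are tallied per
   triple into counts by zone and, inside the abstract, by sentence-location
   class. A pair seen exactly once in the body and never in the title or
   abstract is dropped as incidental; abstract-only documents are untouched
   by this rule.
7. **Scoring and ranking.** `CS2 = S1 + S2` for full texts; for
   abstract-only records `CS1 = 10 × title pairs + S1 + boost`, where the
   boosting-up factor is the median S2 of the batch's open-access full
   texts. Documents are ranked per association by descending confidence.

The model's central assumption is that *where* a pair co-occurs is a proxy
for how central the association is to the paper: titles and result-bearing
locations carry new findings, introductions carry background. The weights
encode that heuristic; they are not fitted.

## Parameters and defaults

| Parameter | Default | Unit / meaning |
|---|---|---|
| sentence-location weights | first/second 2, last 5, other 3 | multiplier per abstract co-occurrence |
| section weights | title 10, results/figure/table 5, discussion/conclusion 2, introduction/case study/appendix/other 1 | multiplier per body co-occurrence |
| gene-in-abstract coefficient | 0.2 | added to S1 per target mention in the abstract |
| minimum surface length | 3 characters (Unicode) | dictionary refinement |
| short-form constraints | all-uppercase, length < 6 | abbreviation candidate |
| G1 threshold | > 3 body occurrences, OA full text only | gene abbreviation rescue |
| G4 thresholds | ≥ 3 sentences (full text), ≥ 2 (abstracts) | supporting-sentence rule |
| ranking cutoff | top 25 documents | AP/MAP evaluation depth |

The abstract weights reflect a rhetorical regularity of biomedical
abstracts: the final sentence usually states the result, the opening one or
two sentences the background. A one-sentence abstract is therefore classed
`last` (weight 5), and in a two-sentence abstract the second sentence is
`last` — when classes collide, the more result-like class wins.

Keyword lists (disease keywords for rule D2, target keywords for G3,
context keywords for G4) ship with defaults in
`default_disease_keywords()` and friends; the published exemplars are
included verbatim, the tails are this package's choices, and all three
lists are explicit arguments so deployments can replace them.

The common-word stoplist used in dictionary refinement is deliberately an
explicit input with an empty default: which gene names collide with common
English words ("Large", "WAS", "impact") depends on the dictionary release,
so the caller supplies the list rather than inheriting a hidden one.

## Matching and filtering choices

**Case sensitivity.** Surfaces of length ≤ 5 that are all-uppercase in the
dictionary (gene-symbol shaped: "ALS", "WAS", "IGF1") match
case-sensitively; everything else matches case-insensitively. Ambiguity
between short symbols and ordinary words is the dominant false-positive
mode, and case is the cheapest discriminator.

**Word boundaries.** Tokens are alphanumeric runs with internal hyphens;
Greek symbols count as word characters (so the generated "TNF α" variants
match). A match may not begin or end inside a hyphenated token: "IGF1"
does not match inside "IGF1-driven".

**Ambiguous surfaces.** A surface mapping to several identifiers emits one
mention per identifier. Disambiguation is the abbreviation filter's job,
not the matcher's.

**Greek variants.** For each whole-word Greek token (spelled name or
symbol, alpha through omega, both directions) the generator emits the
variant with that single occurrence substituted, plus the variant with all
substitutable tokens replaced. Full per-occurrence combinatorics would grow
exponentially on pathological surfaces for no practical gain — real
dictionary terms rarely carry more than one Greek token. The length and
stoplist filters run before variant generation and variants inherit both.

**Long-form window.** The potential long form of a short form `XYZ` is the
up-to-`N+1` words immediately before the parenthesis, `N` being the short
form's character length — the standard Schwartz–Hearst window. Because the
window may start a word early, the dictionary/enzyme match rule (G2) tests
every trailing word sequence of the window rather than the window verbatim.
A short form annotated without any detectable long-form pattern is left
untouched: the filter acts only on pattern-matched candidates.

**Scope of a drop decision.** Dropping an abbreviation removes all mentions
of that surface and kind in the *same document* only. An abbreviation can
be a false positive in one article and genuine in the next, so corpus-wide
suppression would be wrong.

**Rule bookkeeping.** Decisions record the first rule that fired (D1, D2 /
G1..G4 in order). Because the rule set is a disjunction, order affects only
the label, never the kept/dropped outcome.

## Numerical conventions

* Offsets are 0-based and half-open everywhere (sentence `char_start`,
  mention spans).
* The boosting-up factor uses the standard median (mean of the two middle
  values for even batches); an empty full-text batch yields 0, so
  abstract-only corpora still score.
* Ranking ties break by ascending document id, making output byte-stable
  across reruns.
* Average precision normalises by the number of relevant documents *within
  the cutoff* (evaluation is over the top 25 documents); a ranking with no
  relevant document in the cutoff has AP 0.
* `score_correlation()` is Pearson's r over shared document ids and
  refuses degenerate input (fewer than two shared documents, zero
  variance).
* Section tagging is a case-insensitive keyword table with fixed
  first-match precedence (results > discussion > conclusion > methods >
  introduction > case study > appendix > references > acknowledgements >
  competing interests > author contributions > supplementary), so compound
  headings like "Results and Discussion" resolve deterministically to the
  more result-like zone.
* The title is scored inside S2 with weight 10 for full texts; the same
  constant multiplies the title term of CS1 for abstract records. The
  abstract zone never enters S2 — it is S1's domain, and CS2 = S1 + S2 uses
  each exactly once.
* "Gene in abstract" counts mentions, not a binary flag; the coefficient
  is configurable, so a binary variant is one override away.

## The synthetic corpus

`generate_corpus()` builds documents from fixed sentence templates
("TGX1 is associated with morbidity type 2 in this cohort.") with planted
per-zone co-occurrence counts, misleading-abbreviation documents, and three
distractor species that each trip exactly one document-level filter. Every
plan's expected post-filter association record is computed by construction,
so end-to-end tests compare pipeline output against exact ground truth, and
a fixed seed makes the corpus byte-identical across runs.

The generator emulates structure, not language: sentence boundaries are
unambiguous, surfaces never collide with filler text, and co-occurrence
always signals a genuine planted association. Passing tests therefore
demonstrate that the *mechanics* — splitting, matching, filtering,
counting, weighting, ranking — are exact. They say nothing about
performance on real prose, where sentence splitting is noisy, dictionary
surfaces collide with ordinary words in ways the stoplist must catch, and
co-occurrence is only a proxy for assertion. The test suite runs the
mention-walking score oracle over a 100-document seeded corpus and exact
ground-truth recovery over mixed corpora of a few dozen documents; these
sizes exercise every code path while keeping the default suite fast.

## Known limitations

* Co-occurrence carries no polarity: "X is *not* associated with Y" counts
  like an assertion. Relation classification is out of scope.
* The heading classifier is a keyword table, not a trained section tagger;
  unusual headings fall to `other` (weight 1) rather than being guessed.
* Species are not disambiguated; a human dictionary applied to veterinary
  text will mis-ground symbols.
* The harmonic-sum aggregation of evidence *across* documents into a
  single association score is a platform-level concern and intentionally
  not implemented here; the package stops at per-document confidence.
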