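Package: tdmine
Title: Mining and Scoring Target-Disease Associations in Biomedical Literature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies drug-target (gene/protein) and disease mentions in
    sectioned biomedical documents with refined dictionaries, screens out
    false-positive abbreviations with rule sets, extracts sentence-level
    target-disease co-occurrences under document-level filters, and scores
    and ranks documents per association with section- and sentence-location
    weighted confidence formulas. Includes rank-quality evaluation (average
    precision, mean average precision, score correlation) and a deterministic
    synthetic-corpus generator with planted associations for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
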