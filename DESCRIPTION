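Package: meioscreen
Title: Screening and Scoring Computations for In Vitro Meiosis Induction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for discovering meiosis-inducing regulatory
    factors in stem-cell-derived germ cells: pooled-barcode enrichment
    screening of sorted reporter populations, a panel-based meiosis gene
    score with an explicit Gaussian null validated by permutation, per-cell
    factor-barcode assignment and overrepresentation testing, two-level
    (fractional) factorial effect estimation on logit-transformed reporter
    fractions, and cell-type proportion and stage-onset timecourse analysis.
    Includes a synthetic-data generator with known ground truth that emulates
    every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
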