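Package: distboot
Title: Distributional Bootstrapping of Lexical Categories from Child-Directed Speech
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Longitudinal word-context co-occurrence modelling of tagged
    child-directed-speech corpora, unsupervised leave-one-out nearest-neighbour
    categorization of words into five coarse lexical categories (under cosine or
    range-scaled numeric-overlap distance with a frequency-then-random tie-break),
    per-word distributional predictors (log frequency, log contextual diversity,
    average conditional probability given contexts, median information gain of
    co-occurring contexts), and logistic mixed-effects regressions of
    categorization outcomes on those predictors with AIC-based forward selection
    and mosaic-style error analyses. Ships a synthetic corpus generator that
    emulates multi-corpus longitudinal tagged input with Zipfian frequencies,
    category-selective local contexts, and homographs, so the full analysis runs
    without access to the original transcripts.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    data.table,
    lme4,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
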