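Package: handoverNLP
Title: Speech-Recognition Scoring and CRF Information Extraction for
    Clinical Nursing Handover
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking cascaded speech recognition (SR) and
    information extraction (IE) over spoken nursing shift-change handover.
    Provides SCLITE-style word alignment with correct/substituted/inserted/
    deleted counts and word-correctness summaries, Double Metaphone phonetic
    encoding with a phonetic-similarity measure for sound-alike substitution
    analysis, a 50-category structured handover form schema, CRF++-format
    feature files with the associated feature template, a linear-chain
    conditional random field token classifier with random and majority
    baselines, CoNLL-style segment evaluation with leave-one-out cross
    validation, learning curves, leave-feature-out ablation and heading-level
    abstraction comparisons, and a seeded synthetic handover corpus generator
    with speech-recognition-style corruption for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
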