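Package: protlogic
Title: Protein Function Prediction from Literature by Predicate Logic
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
                  email = "maintainer@example.org")
Description: Predicts protein function categories from biomedical text by
    combining statistical term extraction with logic-based inference.
    Biological molecule terms that explicitly co-occur with a protein in
    sentences are extracted by dictionary matching, sentence-level
    pronoun/disconnector relatedness rules and collocation Z-scores;
    additional, implicitly co-occurring function terms are then derived by
    forward-chaining protein specification rules with the ten standard
    inference rules of propositional logic, producing annotated predictions
    backed by checkable natural-deduction proofs. Includes a rule DSL
    parser, a proof checker, a brute-force entailment oracle, evaluation
    metrics with k-fold cross-validation, and a seeded synthetic-corpus
    generator with planted co-occurrence structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
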