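Package: ontocombine
Title: Compound Ontology Design Patterns for Anatomy and Pathology with
    Quantitative Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds compound ontologies that combine an anatomy ontology and
    a pathology ontology through four design patterns (MAP, MAPT, PAM, PAMT),
    classifying them with a structural subsumption rule that emulates a
    description-logic reasoner on this axiom fragment.  Provides the
    quantitative evaluation repertoire used to compare the patterns:
    OQuaRE structural metrics (tangledness, mean and maximum leaf depth),
    Resnik information-content similarity with best-match-average aggregation,
    clustering purity with area under the purity curve, per-individual ROC
    analysis, hypergeometric over-representation with permutation family-wise
    error control, and rank-based statistics (Kendall's tau-b, Wilcoxon
    rank-sum).  Includes a synthetic-cohort generator producing
    strain-structured diagnosis tables for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    stats,
    utils
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
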