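Package: surfscore
Title: Surfaceome Cataloging and Integrative Cancer Gene Scoring
Version: 0.1.0
Authors@R:
    person("surfscore", "developers", email = "surfscore@example.org",
           role = c("aut", "cre"))
Description: Builds a catalog of cell-surface ("surfaceome") genes from
    transmembrane-topology predictions, signal-peptide calls and Gene
    Ontology cellular-component annotation; scores genes as oncogene- or
    suppressor-like per tumor type with an integrative S-score over
    mutation, copy-number and expression evidence; classifies tumor
    samples as altered or unaltered per gene and screens genes and k-gene
    alteration signatures for association with overall survival using
    Kaplan-Meier estimation and the log-rank test; clusters score
    matrices and tests hypergeometric term enrichment; and generates
    fully synthetic TCGA-like cohorts with known ground truth so that
    every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
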