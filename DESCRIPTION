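Package: prareminer
Title: Mining and Structural Annotation of Potentially Recently Active
    Retand LTR-Retrotransposons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for discovering and characterizing
    potentially recently active Retand elements (PRAREs), a lineage of
    plant Ty3/gypsy LTR-retrotransposons with an unusually long internal
    region. Finds reverse-transcriptase (RT) domains by seeded six-frame
    translated Smith-Waterman search, assigns candidates to the Retand
    lineage with a neighbor-joining phylogeny against a model RT panel,
    reconstructs full elements by identical-LTR and target-site-duplication
    criteria, clusters elements by LTR identity and applies the 2%
    size-deviation filter that defines PRAREs, annotates sense/antisense
    ORFs, protein domains (including the antisense TRP28 domain), the
    POL-3'LTR region and tandem-repeat arrays, and reports per-cluster
    consensus sequences, conservation profiles and summary statistics.
    Includes a synthetic-genome generator that plants Retand-like elements
    and decoys with machine-readable ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
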