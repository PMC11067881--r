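Package: orthoclades
Title: Orthogroup Taxon-Specificity, Gene-Family Dynamics, Macrosynteny and
    Marker Evolutionary Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream comparative-genomic analyses over OrthoFinder-style
    orthogroup tables and a rooted species tree: classifies each orthogroup's
    taxon specificity against a ladder of named clades, partitions each
    proteome into lineage-specificity categories, counts exclusive orthogroup
    overlaps between major groups, summarises per-branch gene-family
    expansions and contractions from leaf plus ancestral counts (with a
    linear-cost parsimony fallback for ancestral states and a Welch test of
    terminal versus internal branches), clusters scaffolds of a genome pair
    into putative linkage groups from shared-orthogroup enrichment, and
    profiles the evolutionary age of single-cell cluster marker genes. A
    synthetic-data generator with machine-readable ground truth exercises
    every stage without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    igraph,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    IRanges,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    knitr
Config/testthat/edition: 3
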