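Package: plastgap
Title: Indel Scoring and Outgroup Sensitivity Analysis for Plastome
    Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the bespoke computational steps of plastid
    phylogenomics at the whole-genome scale: construction of analysis
    matrices from plastome alignments (region excision, gap-column
    stripping with full column provenance), cataloguing of indel events
    under explicit acceptance criteria with slipped-strand-mispairing
    detection, Fitch-parsimony classification of indel characters as
    putative synapomorphies or homoplasy against a reference tree with
    per-clade tabulation, and a randomized outgroup-jackknife congruence
    test with a built-in neighbor-joining backend.  A seeded simulator
    generates clock-like trees, plastome-like sequences and ground-truth
    indel events so the entire pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
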