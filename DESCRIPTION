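Package: plastshift
Title: Plastid Genome Quadripartite Structure, IR Junction Dynamics, and
    Supermatrix Site Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of plastid genome (plastome)
    structure: exact detection of the inverted-repeat pair and partition of a
    circular plastome into LSC/IRb/SSC/IRa, localization and classification of
    the four IR junctions relative to gene annotation, screening of intergenic
    spacers for junction-shift insertions (including hidden, non-coding
    insertions carrying psbA/trnH pseudogene fragments), in-silico PCR surveys,
    junction coverage-depth quality control, detection and correction of small
    hairpin-flanked inversions in multiple sequence alignments, and supermatrix
    site statistics (parsimony-informative site counts, Fitch parsimony length,
    consistency/homoplasy indices, site concordance factors, and per-branch
    putative synapomorphies). A synthetic-plastome generator with ground-truth
    records makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
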