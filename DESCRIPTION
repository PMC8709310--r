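Package: dhnkit
Title: Comparative Genomics of Dehydrin Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative-genomic analysis of dehydrin (group-2 LEA)
    gene families: conserved-segment scanning and architecture classification
    of dehydrin proteins, ProtParam-style biochemical descriptors, tandem and
    segmental gene-duplication calling from locus coordinates, identity-based
    clustering of multi-ecotype gene panels, position-weight-matrix promoter
    scanning around transcription start sites, nonparametric drought-response
    differential-expression and trait statistics, climate-niche classification
    by principal components, and phylogenetic-signal estimation (Blomberg's K,
    Pagel's lambda). A synthetic-data module generates every input with known
    ground truth so the whole pipeline is testable without external genomes or
    RNA-seq.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    phytools,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
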