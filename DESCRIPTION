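Package: panpheno
Title: Reference-Centric Comparative Genomics and Geno-Phenotype Typing of
    Bacterial Strain Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reference-centric comparative analysis of bacterial
    strain collections, modelled on the pan/core-genome study design used
    for Lactobacillus rhamnosus: ortholog presence/absence calling of
    reference genes from strain sequences (k-mer anchored local alignment
    with identity and coverage thresholds), shared-content and core-genome
    statistics with a core accumulation curve, gene-content clustering and
    SNP distance trees, detection of hyper-variable chromosomal regions
    (lifestyle islands) from gene-loss frequencies, CRISPR spacer
    oligotyping with protospacer search, growth-curve inhibition statistics
    (area reduction percentage), and an integrated geno-phenotype
    classifier separating dairy-adapted (A) from intestinal-adapted (B and
    B-delta-spaCBA) strains. A synthetic cohort generator with recorded
    ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    ape,
    vegan,
    pracma,
    jsonlite,
    yaml,
    rtracklayer,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust,
    readxl,
    withr
Config/testthat/edition: 3
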