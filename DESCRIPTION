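Package: srnahyb
Title: Genotyping and Small RNA Locus Analysis of Interspecific Solanum Hybrids
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing small RNA and gene expression changes in
    interspecific Solanum lycopersicum x S. pennellii hybrids from count-level
    sequencing data. Provides RNA-seq-based genotyping of recombinant selfing
    pedigrees via per-SNP allele calls smoothed with a 3-state hidden Markov
    model (Viterbi decoding), tiling of genomes into 200-nt small RNA loci with
    transposable-element annotation (including endogenous pararetroviruses),
    negative-binomial likelihood-ratio differential expression with TMM
    normalization and four-class FDR assignment, cross-lineage overlap and
    feature enrichment statistics, DCL2-dependency cross-classification with
    size-class profiles, and a synthetic-data generator with a known truth
    ledger so every stage can be validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    edgeR,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    readr,
    stats,
    S4Vectors,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
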