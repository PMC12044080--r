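Package: blockqtl
Title: Recombination-Block QTL Mapping for Low-Coverage F2 Intercrosses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Genome-wide quantitative trait locus (QTL) mapping for F2
    intercrosses of inbred strains sequenced at ultra-low coverage.
    Provides a forward simulator of biparental crosses with planted QTLs,
    windowed allele-count aggregation, a three-state hidden Markov model
    (Viterbi) for genotype and crossover decoding, cohort-wide
    recombination-block genotype matrices with segregation diagnostics,
    a single-variance-component linear mixed model association scan with
    permutation-based false discovery rate thresholds, and linkage
    disequilibrium based collapsing of significant blocks into
    fine-mapped, gene-annotated, candidate-ranked loci.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
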