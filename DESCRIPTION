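Package: radbubbles
Title: Reference-Free SNP and Indel Discovery from RAD-Seq Reads via de
    Bruijn Graph Bubbles
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: De novo detection of SNPs and short insertions/deletions from
    demultiplexed RAD-Seq read sets without a reference genome and without
    any read clustering. Variants are found as bubbles in the de Bruijn
    graph built from all samples pooled, including RAD-specific
    symmetrically truncated bubbles caused by variants close to locus
    extremities. Reads are mapped back onto bubble sequences to obtain
    per-sample allele coverage, genotypes are called by binomial maximum
    likelihood, paralog-induced variants are flagged by a Phi-coefficient
    rank score, and variants are grouped into RAD loci by shared
    (k-1)-mers between context-extended bubble sequences. A RAD population
    simulator (restriction digest, population/individual SNP injection,
    error-prone read generation) and a recall/precision evaluator are
    bundled so the whole pipeline can be exercised end to end on synthetic
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
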