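Package: dnmtrio
Title: Genome-Wide Characterization of De Novo Mutations in Trio Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, simulation-backed re-implementation of a genome-wide
    de novo mutation (DNM) characterization pipeline for parent-child trio
    whole-genome sequencing studies. Covers somatic/germline classification by
    allelic fraction, clustered-DNM detection and parent-of-origin contrasts,
    paternal-age mutation models, mutation-rate elevation near de novo CNVs,
    trinucleotide (96-channel) mutation spectra, a two-tier damaging-variant
    classifier, a GC-corrected case-control logistic burden test with gene-set
    Fisher burden, and a methylation outlier sample test (MOST) combining
    parallel-analysis PCA retention, covariate adjustment and Grubbs testing
    with a dual FDR rule. A synthetic-data module generates trio cohorts,
    reference sequence, predictor scores, CNVs and methylation matrices with
    known ground truth so every stage is testable without access-controlled
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Rcpp,
    Biostrings,
    BiocGenerics,
    IRanges,
    S4Vectors,
    GenomicRanges,
    vcfR,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
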