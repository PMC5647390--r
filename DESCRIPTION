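Package: taMiner
Title: Genome Mining for mazEF/pemIK-Family Toxin-Antitoxin Operons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained pipeline for discovering type II
    toxin-antitoxin (TA) operons of the mazEF/pemIK family in bacterial
    genome assemblies. Provides naive six-frame ORF detection with
    alternative start codons, an exact Smith-Waterman protein alignment
    engine with BLOSUM62 scoring and Karlin-Altschul E-value estimates,
    position-specific score matrix (PSSM) construction and search, five
    homology-search strategies (conservative iterative cascade, extensive
    single-pass, PSI-style iterative PSSM refinement, RPS-style domain
    profile scan, and DELTA-style profile-mediated search), operon
    arrangement filtering, single-linkage homologue grouping, occurrence
    summaries, and host-association statistics. A synthetic-genome
    simulator plants TA operons and decoy loci with exact ground truth so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
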