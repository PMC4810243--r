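Package: trnaome
Title: Comparative tRNAome Statistics, Genetic Code Combinatorics and
    Wobble Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of transfer-RNA gene sets
    (tRNAomes): pairwise base-difference statistics from unit-cost global
    alignment, the alloacceptor distance index of tRNAome primitivity,
    Fitch-Margoliash least-squares distance trees, codon-box and wobble-stage
    classification of anticodon usage, exact combinatorics of alternate
    genetic codes, permutation tests for codon-domain contiguity of
    biosynthetically related amino acids, and a logistic model of
    metabolite-driven functional-RNA enrichment.  Includes a seeded
    duplication-divergence simulator of GC-rich tRNA-like gene families so
    every analysis stage is testable without external genome data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    phangorn,
    pracma,
    deSolve,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
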