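Package: HapCorrect
Title: Haplotype-Aware Error Correction of Noisy Long Reads via Variation Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Self-correction of noisy long sequencing reads (PacBio CLR or
    Oxford Nanopore, 5-15% error) that preserves haplotype- and
    strain-specific variation. Reads are corrected in two cycles. In each
    cycle, all-vs-all overlaps are computed and filtered, a read alignment
    pile is built per target read and cut into 500-bp windows, and a
    partial-order-alignment variation graph is constructed per window. In
    the first cycle, error-induced edges are pruned from the graph with
    Support and Confidence statistics borrowed from frequent itemset
    mining, and the target subread is realigned against the pruned graph.
    In the second cycle, overlaps are restricted to the same haplotype via
    a sequence-identity threshold and a heaviest-bundle consensus removes
    residual random errors. Includes a simulator for haplotype mixtures
    with long-read error profiles and an internal evaluator (error rate,
    haplotype coverage, SNP concordance).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Sequencing, Alignment, ErrorCorrection, LongRead
RoxygenNote: 7.3.3
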