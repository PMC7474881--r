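Package: overbin
Title: Overlap-Graph Read Binning with Robust Degree Filtering for Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale metagenomic read binning built on an all-vs-all read
    overlap graph. Reads are nodes, pairwise ungapped alignments of at least b
    bases are edges, candidate bins are connected components, and promiscuous
    reads are removed automatically with a median-absolute-deviation (MAD)
    filter on the per-bin edge-degree distribution. Includes quality trimming
    and FASTA/FASTQ input/output, paired-end overlap merging with a forced
    NNN-spacer fallback, 16S rRNA read screening against a reference set, an
    iterative minimum-overlap (b) schedule with block-wise processing, a
    synthetic community simulator with ground-truth labels, bin
    purity/completeness evaluation, and a dependency-driven pipeline executor
    with serial and local-parallel backends.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    parallel,
    Rcpp,
    stats,
    tibble,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
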