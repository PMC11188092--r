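Package: polswap
Title: Detection of DNA Polymerase Gene Swapping in Tailed Phage Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative-genomics pipeline for detecting in-situ swapping of
    DNA polymerase (DNAP) genes among tailed bacteriophages. Builds a
    whole-genome distance from reciprocal-best-hit coverage between ORF
    complements, reconstructs and ultrametrizes a genome tree, decomposes it
    into genus-level subtrees at a fixed depth, annotates DNAP family and
    clade for every predicted protein against labelled references, infers the
    minimal set of polymerase replacement events by small parsimony, and
    validates swap scenarios with an Approximately Unbiased test of
    constrained versus unconstrained marker-gene topologies. Includes a
    synthetic phage-clade generator that plants ground-truth swap events, and
    fragment-based average nucleotide identity for close genome pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    phangorn,
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
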