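Package: tbescan
Title: Annotation and Molecular Evolution of Telomere-Bearing Element
    Transposons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide annotation and evolutionary analysis of
    telomere-bearing element (TBE) transposons, the Tc1/mariner DNA
    transposons of stichotrich ciliate germline genomes. Provides a
    six-frame translated Smith-Waterman search of transposase protein
    queries against an assembly, assembly of translated hits into complete
    and partial elements, terminal-inverted-repeat and target-site
    duplication detection, Markov clustering of elements into families,
    frameshift-aware protein-guided coding-sequence extraction under the
    ciliate nuclear genetic code (translation table 6), Nei-Gojobori
    pairwise dN/dS estimation with a counting-based test of purifying
    selection, and chi-squared tests of element enrichment near annotation
    tracks. A synthetic germline-genome generator with full implant ground
    truth makes every pipeline stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
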