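Package: gapclosr
Title: Gap Closing in Draft Genome Scaffolds with Bloom Filter de Bruijn
    Graphs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Closes runs of unknown bases (N-gaps) inside draft assembly
    scaffolds by local reassembly from whole-genome shotgun reads. K-mers
    from the reads are stored in a multiplicity-thresholded cascading
    Bloom filter that is queried as an implicit de Bruijn graph; the
    flanking sequences of each gap are connected by a depth-limited,
    bidirectional, breadth-first graph search, alternate paths are merged
    into an IUPAC ambiguity consensus, and successful connections are
    spliced back into the scaffolds over a subtractive sweep of k-mer
    sizes. Includes a paired-end read and gapped-draft simulator with
    known ground truth, and an assessment module for closure counts and
    insertion accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
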