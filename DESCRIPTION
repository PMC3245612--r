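Package: fusescan
Title: Split-Read Discovery of Fusion Transcripts in RNA-Seq
Version: 0.1.0
Authors@R:
    person("fusescan", "developers", email = "fusescan@example.org",
           role = c("aut", "cre"))
Description: Detects fusion transcripts (inter-chromosomal, large
    intra-chromosomal and inversion events) from RNA-seq reads by
    segment-split alignment against a k-mer genome index, base-pair
    breakpoint refinement, re-mapping of read segments against spliced
    fusion contigs, stitching of segment placements into full-read
    alignments admitting introns, small indels and at most one fusion,
    a cascade of false-positive filters (anchor length, multi-mapping,
    genomic distance, read support, junction 23-mer repeats, gene
    annotation, 600-bp coverage window), and a read-distribution score
    used to rank the surviving candidates. Includes a deterministic
    simulator of toy genomes, annotations and error-bearing reads with
    planted fusions so that every stage is testable without external
    data, plus a command-line interface over the whole pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
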