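Package: rhtmap
Title: Seed-and-Extend Alignment of Noisy Long Reads with a Regional Hash
    Table
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Maps noisy single-molecule long reads against a reference
    sequence with a seed-and-extend strategy built on a Regional Hash
    Table: overlapping reference windows indexed by a CSR-style k-mer to
    window-number map. Candidate regions are aligned exactly under a
    2-piece affine gap model, implemented both in the classic row-column
    order and in a diagonal-antidiagonal wavefront layout with bulk lane
    updates, verified against each other. Includes static, dynamic and
    integrated load-distribution strategies for sharding FASTQ input
    across a local worker pool with byte-precise record boundary
    relocation, an analytic host/device communication cost model, parallel
    speedup and efficiency metrics, and a noisy long-read simulator with
    ground truth for recall evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    parallel,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
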