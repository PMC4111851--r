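Package: sdcnv
Title: Segmental Duplication and Copy Number Variation Discovery from
    Read Depth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrated discovery of segmental duplications (SDs) and
    copy number variants (CNVs) from whole-genome sequencing read depth.
    Implements whole-genome assembly self-comparison (WGAC) with k-mer
    seeding and banded chaining, a whole-genome shotgun sequence
    detection (WSSD) read-depth caller with a mappability-aware
    "unique-hit" window definition that corrects the fragmentation bias
    introduced by hard masking, GC-bias correction, iteratively trimmed
    control statistics, the 6-of-7 sliding-window duplication/deletion
    rule, copy-number estimation, cross-individual CNV region (CNVR)
    construction, hotspot detection, gene copy numbers, and
    permutation-based interval enrichment with GC breakpoint analysis.
    Ships a synthetic-genome simulator with known CNV truth and an exact
    multi-mapping read aligner so the whole pipeline is testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    generics,
    withr,
    jsonlite,
    yaml,
    Rcpp,
    IRanges,
    S4Vectors,
    Biostrings,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    optparse,
    igraph
Config/testthat/edition: 3
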