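Package: siderscan
Title: Discovery and Validation of HDV-Like Ribozymes in Trypanosomatid Mobile Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for annotating Pr77-hallmark HDV-like
    ribozymes inside trypanosomatid non-LTR retrotransposons. Provides a
    seed-and-extend local aligner for hallmark homology screening with
    iterative re-querying, a structural descriptor that validates the
    HDV-like ribozyme architecture (helices P1, P2, P4 and pseudoknots
    P1.1, P3) and reports concrete base-pair assignments or coded
    violations, mobile-element context filters (downstream poly-A tracks,
    7-11 nt target-site duplications) with SIDER1/SIDER2/DIRE/NAR
    classification, two-phase exponential cleavage-kinetics fitting with a
    competing hyperbolic model, and a synthetic-data generator that plants
    ground-truth elements in simulated genomes so every stage is testable
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    rtracklayer,
    S4Vectors,
    GenomicRanges,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    generics,
    ggplot2,
    minpack.lm,
    withr,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
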