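Package: neotad
Title: Regulatory Reallocation After Structural Rearrangement of a
    Developmental Gene Locus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study how structural variants rewire long-range gene
    regulation at CTCF-delimited chromatin domains, modelled on the mouse
    HoxD locus. Compiles inversion/deletion/duplication specifications into
    segment maps, builds mutant chromosome sequences, and lifts positions
    and features between wild-type and mutant coordinate systems (with UCSC
    chain export). Clusters oriented CTCF sites into boundary groups,
    predicts the resulting domain partition on either genome, and reports
    enhancer-promoter reassignment. Normalizes, remaps and subtracts binned
    contact matrices between genotypes, computes diamond insulation scores
    and viewpoint (virtual 4C) profiles, and quantifies contact gains with
    bootstrap confidence intervals. Provides bedtools-style interval algebra
    with replicate-consensus and multi-set overlap reports, and
    zero-proportion (dropout) based expression inference for UMI count
    matrices: detection summaries, conditional-detection tests, exact
    hypergeometric depth downsampling, rate and fold-change estimation with
    bootstrap confidence intervals, and correlation-sign reports. Includes
    seeded simulators (toy locus, contact matrices, replicate peak sets,
    UMI counts) so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    Matrix,
    methods,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
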