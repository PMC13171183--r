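Package: invscan
Title: Inversion-Aware Demographic Inference and Barrier Scans from the
    Blockwise Site Frequency Spectrum
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Composite-likelihood inference of two-population divergence and
    effective migration from the blockwise site frequency spectrum (bSFS) of a
    pair of diploid genomes, under strict-divergence (DIV) and
    isolation-with-migration (IM) models.  Supports separate fits for
    chromosomal inversion and colinear regions (inversion age and migration
    contrast), a sliding-window scan for barriers to gene flow calibrated by
    per-window simulated nulls, chi-square enrichment tests of barrier windows
    and candidate SNPs inside inversions, and a circular-resampling overlap
    test between candidate SNP sets and barrier regions.  A structured
    coalescent simulator provides parametric bootstraps, full synthetic
    scenario datasets and a Monte Carlo oracle for the exact bSFS likelihood
    engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    vcfR,
    yaml,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
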