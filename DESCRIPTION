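Package: tiledmr
Title: Cell-Type Differential Methylation Analysis for Promoter Tiling Arrays
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of MeDIP promoter tiling-array experiments
    with a paired two-cell-type design: probe-level normalization (log2,
    per-array spatial median-filter correction, cross-array quantile
    normalization), per-probe paired t-statistics, 300 bp sliding-window
    enrichment scoring with permutation-calibrated false-positive control,
    merging of significant windows into directional differentially
    methylated regions (DMRs), annotation against TSS and CpG-island tracks
    with coverage-corrected positional nulls, histone-signal metaprofiles
    around DMRs with random-placement controls, DMR-set overlap permutation
    testing, and validation-stage statistics on CpG-unit methylation
    matrices. Ships a seeded synthetic-data generator emulating the paired
    promoter tiling design so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
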