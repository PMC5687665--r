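Package: ndsnf
Title: Multi-Omic Cancer Subtyping with Network-Diffused Mutation Profiles
    and Similarity Network Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative discovery of cancer subtypes from multi-omic patient
    cohorts. Sparse binary somatic-mutation profiles are first smoothed by a
    random-walk-with-restart diffusion model over a gene interaction network,
    making them comparable with continuous omics layers (methylation, mRNA,
    miRNA). Per-layer patient similarity networks built with a scaled
    exponential kernel are then merged by similarity network fusion, and the
    fused patient network is partitioned by spectral clustering with eigengap
    model selection. Includes survival (log-rank) and silhouette evaluation, a
    planted-subtype synthetic cohort generator for benchmarking, and
    broom-style tidiers plus ggplot2 autoplot methods for every result type.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    igraph,
    Matrix,
    mclust,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
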