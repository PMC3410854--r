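Package: metachip
Title: Metagene Profiling and Differential Occupancy Analysis for
    ChIP-chip Tiling Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Average-gene ("metagene") analysis of probe-level ChIP-chip
    tiling-array enrichment: strand-aware mapping of probes into scaled
    gene coordinates, profile matrices with missing-data support,
    occupancy-quartile stratification against a reference condition,
    condition-difference profiles with position-wise one-sample t-tests
    and tiered significance shading, mark-to-mark normalization and
    genome-wide correlation, ranked occupancy changes with hypergeometric
    category enrichment, and ChIP-qPCR percent-input quantification.
    Includes a calibrated synthetic-data generator emulating 200-bp
    tiling arrays over a gene-dense genome so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    broom,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
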