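Package: refstab
Title: Reference Gene Stability Analysis for RT-qPCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for selecting stable reference (housekeeping) genes for
    RT-qPCR normalization from quantification-cycle (Cq) data. Implements the
    four standard stability algorithms (geNorm M values with iterative
    exclusion and pairwise-variation analysis, the NormFinder model-based
    variance decomposition, the BestKeeper descriptive index, and the
    comparative delta-Ct method), aggregates them into a comprehensive
    ranking by the geometric mean of per-method ranks, estimates PCR
    amplification efficiency from standard-curve dilution series, validates
    candidate normalization schemes against a target gene with one-way
    ANOVA, and simulates spatio-temporal factorial Cq datasets with known
    ground truth for benchmarking. All user-facing functions take data
    frames and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
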