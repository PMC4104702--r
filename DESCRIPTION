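Package: gxesim
Title: Power Simulations for Gene-by-Environment Interactions in GWAS
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a polygenic quantitative trait whose per-allele effect
    sizes are perturbed by a shift from an "ancestral" to a "modern"
    environment, and measures the downstream consequences for genome-wide
    association studies: two-stage SNP discovery, per-SNP gene-by-environment
    (GxE) interaction tests, and unweighted genetic-risk-score-by-environment
    (GRSxE) tests. Provides a seeded synthetic-data generator (architecture and
    cohorts), vectorised association scans, scenario orchestration, a
    parameter-grid runner with heat-map summaries, and tidy outputs throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    graphics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
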