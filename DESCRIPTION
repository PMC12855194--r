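Package: phenoswitch
Title: Bistable Phenotype Heterogeneity in Multicellular Yeast Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of bistable phenotype heterogeneity in
    isogenic multicellular (snowflake) yeast populations. Provides a
    two-phenotype stochastic switching model (large multicellular clusters
    producing small ancestral-like propagules through a sigmoid-gated
    transition), simulation by explicit Euler / Euler-Maruyama integration,
    and grid-search fitting of the model to phenotype-proportion time
    courses. Also implements the particle-size-distribution statistics the
    analysis rests on: two-component Gaussian mixture decomposition by EM,
    a BIC-based bimodality decision, a kernel-density overlap index between
    diameter distributions, Ward-D2 clustering of overlap matrices, and
    threshold classification into small and large size classes. A synthetic
    data generator emulates Coulter-counter diameter exports and phenotype
    count time courses so every stage is testable without instrument data.
License: MIT
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
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    deSolve,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
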