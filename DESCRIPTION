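Package: senosig
Title: Cell-Type Senescence Signatures and Senescence Burden in Plasma Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives cell-type-specific senescence protein signatures from a
    multi-induction differential-expression catalog (senescent versus
    proliferating primary cell types) and quantifies them in plasma-proteomics
    cohorts. Provides the two-induction rule for senescence-associated protein
    (SAP) classification, cell-type-exclusive and core signatures, elastic-net
    panel selection with sign filtering and composite senescence-burden
    scores, covariate-adjusted trait models with repeated and nested
    cross-validation and cross-study transfer, bootstrap causal mediation,
    relative-importance decomposition, decade-balanced downsampling with
    sliding-window differential abundance across the lifespan, left-truncated
    stratified Cox models with proportional-hazards diagnostics, quartile
    lifetime trajectories, and per-signature "seno-ages" with residual age
    gaps. A synthetic-data module generates catalog, cohort, and tissue-atlas
    inputs with planted ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tidyselect,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
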