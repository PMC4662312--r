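Package: zonedemog
Title: Zone-Based Demographic Analysis of Tree Species Ranges
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Derives plot-level demographic indices from forest-inventory
    records -- importance value (relativized abundance), percent mortality,
    and seedling count -- aggregates them to grid cells, and splits a species'
    range into cold-leading, core, and warm-trailing climatic zones from an
    average annual extreme-minimum-temperature surface (plant hardiness
    zones).  Per zone it fits regression trees with cost-complexity pruning,
    multivariate regression trees over the joint demographic response, and
    randomized tree ensembles with category-grouped permutation importance;
    decision-tree rules fitted at coarse resolution can be applied to
    fine-resolution predictor grids to map regional species groups.
    Includes a synthetic-landscape generator with spatially autocorrelated
    predictors so the full pipeline is testable without inventory data, and
    the cold-versus-warm zone comparison protocol (subsampling, log
    transformation, F-test gated t-test).
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
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    rpart,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
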