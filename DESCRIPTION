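Package: organclock
Title: Organ-Specific Plasma Proteomic Aging Clocks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Derives organ-specific biological age estimates from plasma
    proteomics. Calls organ-enriched genes from a tissue expression atlas
    (four-fold enrichment rule), trains sparse penalized age clocks per
    organ protein panel with a cross-validated sparsity rule, computes
    z-scored age gaps, classifies extreme-ager ageotypes, and provides the
    downstream association machinery: covariate-adjusted Cox and linear
    models, Benjamini-Hochberg correction, Gini dispersion of log hazard
    ratios, penalized mortality-model comparison, Kaplan-Meier summaries,
    permutation feature importance for biological aging (FIBA), and clock
    distillation onto reduced protein platforms. Includes a synthetic
    survival-cohort generator with correlated latent organ age gaps, a
    proteome emission model, proportional-hazards events, longitudinal
    visits, and missingness, so the whole pipeline is testable without
    restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    survival,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
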