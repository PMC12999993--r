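Package: ecostoich
Title: Ecoenzymatic Stoichiometry Estimation and Spatial Upscaling of Soil
    Microbial Nutrient Use Efficiency
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates soil microbial nitrogen and phosphorus use efficiency
    (NUE, PUE) from extracellular enzyme activities, microbial biomass, and
    soil nutrient pools via an ecoenzymatic stoichiometric model; screens
    observations with interquartile-range outlier flagging and iterative
    variance-inflation-factor predictor selection; gap-fills missing fields
    from gridded covariate layers; compares eight candidate regression models
    by repeated Monte-Carlo cross-validation; and upscales efficiencies over
    covariate grids with a random-forest model, permutation importance with
    one-sided significance tests, partial-dependence curves, per-cell ensemble
    uncertainty, and biome-level summaries.  A synthetic-data generator with
    known embedded drivers provides a recoverable ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    ranger,
    rpart,
    stats,
    tools,
    tree,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
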