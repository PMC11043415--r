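Package: metstab
Title: Stability Analysis for Multi-Environment Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis of balanced multi-environment trials (MET) laid out as
    randomized complete block designs replicated across locations. Provides
    the combined analysis of variance with replicates nested in environments,
    variance-component and broad-sense heritability estimators, the additive
    main effects and multiplicative interaction (AMMI) model with interaction
    principal component scores and Gollob F-tests, six univariate stability
    statistics (AMMI stability value and index, Eberhart-Russell joint
    regression slope, Wricke's ecovalence, Shukla's stability variance, and
    the weighted average of absolute scores with its yield-blended ranking),
    and genotype-plus-genotype-by-environment (GGE) biplot geometry
    (which-won-where sectors, mean versus stability projections,
    discriminativeness versus representativeness, and ideal-point rankings)
    computed as data rather than figures. A simulator for replicated trials
    with a known low-rank interaction supports estimator validation, and a
    report writer plus command-line script tie the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
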