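Package: microspec
Title: Seasonal Microhabitat Specialization of Soil Arthropod Communities
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of seasonal microhabitat use in soil
    arthropod communities, built around bipartite taxon-by-microhabitat
    interaction networks. Implements the complementary specialization index
    H2' and the node-level standardized Kullback-Leibler divergence d' with
    fixed-margin (Patefield RxC) null models, link-temperature
    standardization and permutation-based correlation of consecutive monthly
    networks, abundance-weighted environmental occurrence-niche estimation
    with permutation tests, effective Shannon diversity profiles, and the
    small association statistics (OLS F-tests, Wilks-lambda multivariate
    regression, rank and product-moment correlations) used on monthly
    summaries. A synthetic-data generator emulating a year-long survey of
    three forest microhabitats provides ground-truthed inputs for every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    vegan,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'association-stats.R'
    'community-data.R'
    'diversity.R'
    'fixtures.R'
    'specialization.R'
    'network-dynamics.R'
    'occurrence-niche.R'
    'pipeline.R'
    'synthetic-data.R'
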