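Package: seedtrans
Title: Seed-to-Seed Transmission Analysis of Plant Bacterial and Fungal
    Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Longitudinal analysis of vertical transmission of seed
    endophytic bacterial and fungal communities across plant generations.
    Provides cumulative-sum-scaling and compositional normalizations,
    community dissimilarities, ordination and permutation tests,
    transmitted-OTU detection across seed generations, successional-mode
    classification, niche-responsiveness (heritability-analog) estimation
    from linear mixed models, Sloan neutral community model fitting with
    per-OTU niche/neutral partitioning, expectation-maximization microbial
    source tracking with an unknown source, SparCC-style compositional
    correlation networks with meta-network merging, modularity, hub and
    complexity statistics, and hypergeometric/binomial association
    enrichment.  A synthetic-data module generates full longitudinal
    multi-compartment studies with recorded ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    igraph,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
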