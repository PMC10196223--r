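Package: priogen
Title: Eco-Genetic Conservation Prioritization for Tree Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for eco-genetic conservation
    prioritization of structured tree populations: microsatellite
    diversity and differentiation metrics (allelic richness by
    hypergeometric rarefaction, private alleles, Weir-Cockerham FST),
    landscape-genetics variance partitioning with distance-based
    redundancy analysis (isolation by distance, environment, resistance
    and colonization), linkage-disequilibrium effective population size
    and M-ratio bottleneck inference with a two-phase-model coalescent
    null, a minimal maximum-entropy-style suitability model with
    threshold-area and altitudinal accounting under future climate
    scenarios, ancestry-under-climate forecasting, and two population
    prioritization procedures (greedy allele-complementarity reserve
    selection and a conservation index combining allelic richness,
    forest continuity and projected climate shift). Includes a
    synthetic-data generator producing genotypes, ancestry matrices,
    climate rasters and occurrences with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    glmnet,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    MASS,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
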