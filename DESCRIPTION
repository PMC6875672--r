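Package: streamnet
Title: Co-Occurrence Network Topology for Watershed-Scale Stream Bioassessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds taxon co-occurrence networks from stratified groups of
    benthic macroinvertebrate (BMI) stream samples using a richness-preserving
    permutation null model with standardized effect-size (SES) edge scoring,
    computes five network topology measures (size, connectance, mean
    co-occurrence strength, modularity, degree heterogeneity), and models mean
    biotic-integrity index scores (CSCI) from those measures with
    AIC-based backward elimination, repeated k-fold cross-validation and
    LMG relative-importance decomposition. Includes a watershed-structured
    community simulator with known stress effects so the whole pipeline is
    testable end to end without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
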