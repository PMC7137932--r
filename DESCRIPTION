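Package: nichepack
Title: Trait-Based Community Assembly Analysis with Convex-Hull Null Models
Version: 0.1.0
Authors@R:
    person("Niche", "Pack Developers", email = "nichepack@example.org",
           role = c("aut", "cre"))
Description: Pipeline for trait-based community assembly analysis of
    small-mammal metacommunities: specimen-level morphometric ingestion with
    trapping-session selection, ratio-transformed trait derivation with
    1.5*IQR outlier screening, Gower distances and principal coordinates
    trait space, convex-hull functional richness (FRic) and mean
    nearest-neighbour distance (MNND), richness-preserving null models with
    total/regional species pools and hull-constrained pool variants,
    standardized effect sizes, Wilcoxon signed-rank and type-II ANCOVA
    inference, and a synthetic metacommunity generator with neutral,
    environmental-filtering and limiting-similarity assembly scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
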