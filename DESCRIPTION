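Package: ambnet
Title: Social Network Analysis of Ambulatory Physician Referral Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds directed, weighted physician patient-sharing networks from
    visit-level administrative claim records, where an edge links two physicians
    whenever a patient consults one and then the other within a configurable
    7-45 day referral window. Computes network- and vertex-level measures
    (density, efficiency, PageRank, Kleinberg hub/authority scores, subgraph
    centrality, and others), derives physician profiles in three managerial
    dimensions (centrality, relationship with authorities, patient follow-up)
    by K-means clustering with data-driven cluster counts, detects medical
    communities with the map-equation (Infomap) algorithm, and provides the
    association statistics used to characterize them (chi-square tests with
    adjusted standardized residuals, rank and mean comparisons, Bonferroni
    control). Includes a synthetic claims generator with planted community and
    archetype structure so the full pipeline is testable without access to
    proprietary insurer data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    broom,
    cluster,
    dplyr,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
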