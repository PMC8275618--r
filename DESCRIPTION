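Package: qicd
Title: Quantum-Inspired Community Detection for Biodiversity Change Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds attribute-driven networks over administrative units that
    harbor a focal species (tiger populations across Indian states), detects
    communities with three quantum-inspired algorithms (binary and real-coded
    quantum-inspired evolutionary algorithms and a quantum-behaved discrete
    particle swarm) plus a native Girvan-Newman baseline, evaluates partitions
    with modularity, normalized mutual information, adjusted Rand index and
    degree/betweenness centralities, and statistically correlates detected
    communities with land-use and climate drivers via Pearson's test. Includes
    a synthetic-data generator emulating the study design, a mixing-parameter
    sweep harness, and an NSGA-II parameter tuner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
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
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
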