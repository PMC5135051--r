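Package: antnets
Title: Multilayer Ant-Plant Interaction Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted bipartite interaction networks from long-format
    ant-plant interaction event tables, one layer per plant-derived resource
    type (extrafloral nectar, flowers, fruits, trophobiont honeydew, visits),
    and analyses their structure. Implements network-level complementary
    specialization (H2'), weighted nestedness (WNODF), Morisita-Horn niche
    overlap, and weighted bipartite modularity maximised by simulated
    annealing, with fixed-margin (Patefield) null-model significance,
    standardized modularity, and Monte-Carlo comparison of resource layers.
    Per-site network descriptors are compared with Poisson generalized linear
    models, and the composition of each layer's core of high-degree species is
    compared across layers with PERMANOVA and nonmetric multidimensional
    scaling. A synthetic community generator with planted structure supports
    calibration and end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
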