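Package: MicroFoodWebs
Title: Construction, Topology and Stability of Microbial Food Webs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds genus-level microbial food webs from protist and
    bacterial community tables together with a literature-compiled
    predator-prey interaction catalog and trophic functional-group
    annotations. Quantifies web complexity (links, linkage density,
    connectance), topology (clustering coefficient, characteristic path
    length, modularity), trophic structure (prey-averaged trophic levels,
    omnivory) and stability (quasi sign-stability from Monte Carlo sampling
    of sign-constrained community matrices). Compares empirical webs against
    curveball degree-preserving null ensembles with Kolmogorov-Smirnov
    tests, derives per-sample sub-network features (average degree,
    bacterivore-bacteria interaction proportion, Shannon diversity), and
    relates them to web metrics. A seeded synthetic-data generator emulates
    seasonal subalpine-lake community data so the whole pipeline runs
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    vegan,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
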