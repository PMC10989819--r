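Package: micromark
Title: Neural-Network and Random-Forest Discovery of Disease-Associated
    Microbial Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies disease-associated microbial markers from
    case/control relative-abundance profiles by combining random-forest
    permutation-importance ranking with a top-k sweep scored by the
    cross-validated AUC of a lightweight dense neural network. Includes
    directed marker-marker interaction network inference by per-target
    tree-ensemble importances with a row-variance refinement, neural-network
    regression of clinical covariates (fasting blood glucose, BMI, age,
    weight) from marker abundances, covariate-quantile stratification of
    marker abundance patterns, per-feature Kruskal-Wallis testing, and a
    synthetic cohort generator with planted ground truth so every stage can
    be exercised without external data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    graphics,
    ranger,
    e1071,
    class,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
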