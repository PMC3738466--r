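Package: popcode
Title: Multivariate Analysis of Visual Object Representations in Neural Populations
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to characterise how a population of visually driven neurons
    represents a set of object images. The package generates synthetic stimulus
    sets (isolated grayscale objects with near-identical "twin" exemplars) and
    Poisson spiking populations tuned to image properties; computes low-level
    image properties (luminance, contrast, area, aspect ratio) and
    HMAX-style C2 shape features; builds semantic, shape-based and low-level
    category hypotheses; clusters population response vectors with hierarchical
    agglomerative clustering, k-means with BIC/AIC model selection, PCA, and a
    bounded-depth minimum-spanning-forest (D-MST) algorithm with stability
    scanning and consensus forests; scores cluster-category overlap with
    twin-aware permutation nulls and a connected-subtree search; and decodes
    category membership with cross-validated Fisher linear discriminants on
    constraint-pruned categories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
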