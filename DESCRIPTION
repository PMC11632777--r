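Package: aabba
Title: Atom-Atom, Bond-Bond and Bond-Atom Autocorrelation Kernels for
    Attributed Molecular Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Featurization of attributed molecular graphs, in particular
    transition-metal complexes, by Moreau-Broto style autocorrelations
    extended from the classical atom-atom form to bond-bond and bond-atom
    terms (the AABBA graph kernel).  Graphs carry per-atom and per-bond
    property tables and an optional metal-center flag; autocorrelations
    support product, deltametric, ratiometric and summetric operators,
    full or metal-centered origins (with a merged "super-bond" origin for
    bond-bond terms), and arbitrary maximum depths.  The package also
    provides the evaluation harness used to benchmark such fingerprints:
    a multilayer-perceptron regressor, a gradient-boosting ensemble with
    impurity-based feature relevance, a Gaussian-process regressor with a
    multiplied Linear x RBF kernel, accumulated-relevance dimensionality
    reduction, and a deterministic generator of metal-complex-like
    synthetic graphs with planted regression targets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
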