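Package: scrqsar
Title: Consensus QSAR Modelling with Atom-Neighbourhood Descriptors and
    Self-Consistent Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for consensus QSAR modelling of enzyme
    inhibitors, built around two substructural descriptor families --
    Multilevel Neighborhoods of Atoms (MNA) string counts and Quantitative
    Neighborhoods of Atoms (QNA) per-atom (P, Q) pairs -- together with
    three whole-molecule descriptors (topological length, topological
    volume, lipophilicity).  Partial regression models are fitted by
    self-consistent regression (ridge-stabilised least squares with
    iterative elimination of insignificant variables) or by radial basis
    functions on the selected variables, and averaged into consensus
    models with an applicability domain.  The package also provides
    ranked-set train/test splitting, leave-many-out cross-validation, a
    full external-validation metric suite (rm2 family, CCC, QF1^2/QF2^2,
    MAE/RMSE/B criteria with 95%-trimmed variants), dose-response percent
    inhibition and IC50 linear interpolation, and a seeded synthetic-data
    generator with planted descriptor-activity structure for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
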