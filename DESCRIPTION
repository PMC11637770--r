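Package: gdidelim
Title: Genealogical Divergence Index and Heuristic Species Delimitation
    Under the Multispecies Coalescent with Migration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes the genealogical divergence index (gdi) for pairs of
    populations under the multispecies coalescent model with continuous
    migration (MSC-M), using exact structured-coalescent Markov-chain
    calculations, closed-form expressions for unidirectional and
    ghost-lineage gene flow, and fast coalescent simulation for arbitrary
    migration patterns. Provides hierarchical merge and split heuristics
    for species delimitation on a guide tree, including non-sister merges
    for paraphyletic species, posterior propagation of parameter
    uncertainty with equal-tail and highest-posterior-density intervals,
    and a control-file driven pipeline with pluggable parameter-estimation
    backends.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    Matrix,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'AllGenerics.R'
    'model.R'
    'coalmc.R'
    'closedform.R'
    'simulate.R'
    'gdi.R'
    'delimit.R'
    'interfaces.R'
    'gdidelim-package.R'
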