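Package: coevoring
Title: Coevolution-Guided Contact Inference and Ring Assembly Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores residue coevolution from multiple sequence alignments via
    sparse inverse covariance estimation (graphical lasso) with average
    product correction, validates the resulting couplings against
    structure-derived C-alpha contact maps, selects inter-subunit couplings
    for export as docking distance restraints, and builds and analyses
    n-fold (Cn) symmetric ring models of oligomeric assemblies such as the
    bacterial flagellar MS ring.  A synthetic-data module generates
    alignments with planted coevolving column pairs and toy ring structures
    with known interface contacts, providing ground truth for benchmarking
    every step of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
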