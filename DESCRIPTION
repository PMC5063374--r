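Package: scfc
Title: Structure-Function Coupling and Subspace Analysis of Brain Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how structural connectivity (SC) shapes measured
    functional connectivity (FC) in whole-brain region-level data. Provides a
    synthetic multi-subject cohort generator (hemispheric atlases, shared-core
    SC with subject gains, diffusion-style interhemispheric dropout), five
    SC-driven generative models of regional activity (SAR, rate, Wilson-Cowan,
    Kuramoto, FitzHugh-Nagumo) with a Balloon-Windkessel hemodynamic forward
    model, four families of connectivity measures (Pearson FC, k-nearest-
    neighbour mutual information, 3-way total correlation, windowed dynamic
    FC), a bootstrap-over-subjects SVD engine that extracts reproducible
    linear subspaces with permutation controls, and a proof-of-concept
    inversion that estimates SC from FC through a polynomial map of
    first-dimension projections.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
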