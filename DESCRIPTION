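Package: lipidheat
Title: Imposed-Flux Nonequilibrium Molecular Dynamics and Heat-Transport
    Analysis for Coarse-Grained Lipid Bilayers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale molecular dynamics engine and analysis pipeline for
    studying heat transport across hydrated lipid bilayers. Provides a
    coarse-grained bilayer/solvent builder, an imposed-flux (fixed energy
    exchange) nonequilibrium MD method with exact flux bookkeeping, per-layer
    temperature profiles, segment thermal conductivities, layer and
    interfacial (Kapitza) thermal resistances, gel-fluid phase-transition
    detection from specific-volume curves, and adhesion-energy decomposition
    between molecular groups.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    stats,
    utils,
    tibble
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
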