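Package: duobasin
Title: Dual-Basin Structure-Based Models for Protein Fold-Switching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds all-atom structure-based (Go-like) models from macromolecular
    coordinates, merges two conformations of the same covalent topology into a
    dual-basin model with Gaussian contact and two-well dihedral potentials,
    integrates Langevin dynamics in reduced units, and analyses the resulting
    conformational-switching trajectories with native-contact order parameters
    (Q fractions, interdomain contact breakage, refolding landscapes, event
    detection). Also provides rigid-body geometry descriptors for transcription
    elongation complexes: domain swiveling angles from two-stage superposition,
    DNA duplex helix-axis fits, inter-duplex angles and RNA:DNA hybrid
    diameters, together with synthetic fixtures (a two-state fold-switching toy
    and ideal B-form duplexes) so the full pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
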