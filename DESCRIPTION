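Package: silicabrush
Title: Coarse-Grained Simulation of DNA-Brush-Directed Silica Condensation on Six-Helix-Bundle Origami
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and simulates coarse-grained bead models of six-helix-bundle
    (6HB) DNA origami decorated with single- or double-stranded DNA brushes, and
    analyses how the brushes steer the adsorption of cationic silica precursors.
    Systems are constructed from a compact brush-layout notation, propagated with
    overdamped Brownian dynamics under screened (Debye-Hueckel) electrostatics,
    WCA excluded volume and a short-range precursor-DNA attraction, and analysed
    for regional condensation enhancement, brush residence times, radial brush
    charge profiles, probe electrostatic-energy scans and divalent-salt sweeps.
    A worm-like-chain toolkit generates synthetic contours and estimates
    persistence lengths from tangent-angle correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
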