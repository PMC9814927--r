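Package: xtalmc
Title: Threshold Monte Carlo Exploration of Crystal Energy Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for exploring the lattice-energy landscapes of rigid-molecule
    organic crystals. Implements the threshold (lid-limited) Monte Carlo
    algorithm for estimating energy barriers between crystal packings,
    a rigid-body exp-6 plus Ewald point-charge lattice-energy model with
    three-step pressure-assisted local minimization, duplicate-structure
    detection by simulated powder diffraction screening and molecular-cluster
    comparison, hydrogen-bond motif classification, disconnectivity-graph
    (superbasin tree) construction, Sobol quasi-random crystal structure
    prediction as a reference landscape generator, and atom-centred descriptor
    (ACSF/SOAP-REMatch) featurization with density-based clustering for
    landscape analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
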