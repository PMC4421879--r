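Package: phaseCT
Title: Grating-Interferometer Phase-Contrast Tomography Simulation and
    Densitometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale simulator and analysis chain for X-ray Talbot
    grating-interferometer phase-contrast tomography of soft tissue.
    Generates voxelized mass-density phantoms (fetus-like organ models and
    a stretched two-layer vessel ring), converts them to refractive-index
    decrement volumes, simulates phase-stepping acquisition with fringe
    visibility and Poisson photon noise, retrieves differential-phase
    sinograms with flat-field correction, reconstructs the decrement volume
    by filtered backprojection with a Hilbert-type filter, and converts the
    result to quantitative mass density for ROI statistics, histograms,
    organ volume/mass and density-resolution reports. Also provides the
    closed-form instrument-design calculators (Talbot distances, tilted
    analyser-grating geometry, achromaticity, detector geometry,
    transmission budgets) and the on-the-fly scan scheduler (stepping
    period, rotation speed, trigger timeline with flat-field insertion).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    tiff,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
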