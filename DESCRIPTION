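Package: droptomo
Title: Optical Projection Tomography and Spherical-Harmonic Morphometry for
    Droplet-Rotated Single Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for arrayed-droplet optical
    projection tomography of single suspended cells. Generates synthetic
    rotating nuclear phantoms and their time-lapse projection stacks with
    realistic camera noise and drift, restores pixel-wise temporal signals
    with zero-phase Butterworth filtering, reconstructs isotropic 3D volumes
    by row-wise ramp-filtered backprojection, and quantifies nuclear surface
    shape by spherical-harmonic (SPHARM) expansion with analytic
    Gaussian-curvature concave-fraction spectra. Includes closed-form
    droplet rotation-dynamics and acquisition-planning calculators and a
    centroid drift tracker for time-lapse footage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    igraph,
    jsonlite,
    pracma,
    Rcpp,
    signal,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
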