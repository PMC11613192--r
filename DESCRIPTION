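Package: satomo
Title: Simulated-Annealing 3D Reconstruction from Fixed-Angle Impedance
    Tilt Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs a 3D sample volume from eight simultaneously
    acquired, fixed-angle impedance tilt images (linear-array impedance
    scanning electron microscopy geometry) by simulated annealing with
    localized Gaussian-kernel perturbations, residual-sum-of-squares
    reprojection error, Boltzmann acceptance and exponentially decaying
    temperature, kernel-size and perturbation schedules. Includes the
    matching image preprocessing chain (narrow Gaussian smoothing,
    broad-Gaussian background subtraction, 8-bit conversion), an
    edge-spread resolution estimator, convergence diagnostics, a
    parallel-beam shear-sum forward projector with an incremental
    variant, synthetic phantoms (film-attached spheres, emulsion shell,
    cell with nucleus and granules) with a tilt-series simulator, and
    TIFF/MRC/YAML/CSV readers and writers plus a command-line surface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    yaml,
    optparse,
    stats,
    utils,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
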