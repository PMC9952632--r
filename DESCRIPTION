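Package: archflow
Title: Pulsatile Hemodynamics of Idealized Aortic-Arch Geometries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale computational hemodynamics pipeline for studying
    stent-graft remodeling of the aortic arch. Generates parametric idealized
    arch lumens for four morphological stages (normal, preoperative with a
    saccular arch aneurysm, 1 week and 6 months postoperative), solves
    pulsatile laminar incompressible Newtonian flow with physiological
    velocity-inlet and pressure-outlet waveforms on stabilized linear finite
    elements, and post-processes wall shear stress into time-averaged wall
    shear stress (TAWSS), oscillatory shear index (OSI) and relative residence
    time (RRT) maps with threshold-based atherosclerosis-risk region
    statistics, per-outlet perfusion accounting and centerline curvature
    morphometry.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
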