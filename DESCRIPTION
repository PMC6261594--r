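Package: flapwing
Title: Reconstruction and Aerodynamic Simulation of Flapping Membrane-Wing Flight
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying flapping membrane-wing (bat-style) flight from
    multi-camera motion capture through computational aerodynamics. Generates
    synthetic marker kinematics with closed-form ground truth, reconstructs 3D
    marker trajectories from multi-view 2D observations by pairwise DLT
    triangulation with median fusion and PCA-based cleaning, builds a Delaunay
    control mesh and barycentric fine surface mesh moved by natural cubic
    splines, computes kinematic flight metrics (Strouhal number, plunge
    amplitude, stroke-plane angle, planform-area modulation), drives a
    desk-scale incompressible finite-volume Navier-Stokes solver with dynamic
    Smagorinsky LES and a sharp-interface thin-surface immersed boundary,
    integrates transient aerodynamic force, lift coefficient and power over the
    wing surface, and validates the result against an observed trajectory with
    a lumped-mass Runge-Kutta model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stats,
    utils,
    Matrix,
    deldir,
    yaml,
    jsonlite,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
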