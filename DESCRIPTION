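Package: vesishear
Title: Morphology and Rupture Analysis of Sheared Copolymer Nanovesicles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis toolkit for coarse-grained bead trajectories of
    block-copolymer nanovesicles under shear flow. Reads GRO, LAMMPS dump and
    XYZ configurations, identifies copolymer aggregates by cutoff-distance
    clustering, computes centre-of-mass pair correlation functions,
    gyration-tensor shape and orientation descriptors, enclosed volume,
    surface area and reduced volume, solvent-accessible surface area,
    per-chain end-to-end statistics and configurational entropy,
    contour-resolved bilayer thickness and density profiles, ellipticity
    autocorrelation relaxation times, Weissenberg-number bookkeeping, rupture
    detection and the critical-strain law. Includes a synthetic bead-resolution
    vesicle generator (spheres, ellipsoids, dumbbells, fragments, prescribed
    ellipticity time series) so every stage is testable without molecular
    dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
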