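Package: atriadrift
Title: Monodomain Simulation of Anatomy-Induced Scroll-Wave Drift in
    Idealised Human Atrial Geometries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates re-entrant electrical activity (spiral and scroll
    waves) in idealised three-dimensional human atrial geometries with a
    monodomain reaction-diffusion model of the Courtemanche-Ramirez-Nattel
    human atrial myocyte, including atrial-fibrillation electrical
    remodelling and an acetylcholine-activated potassium current.  Provides
    voxel geometry builders (sheet, strand, wedge, ridge, pectinate-muscle
    bridges), scroll-wave initiation by the phase-distribution method,
    filament extraction as the broken-line intersection of two isosurfaces,
    epicardial tip tracking with rotation averaging and drift
    classification, and action-potential trace analytics (power spectra,
    recurrence maps, conduction velocity, breakthrough detection).  The
    numerical core is compiled for speed; results are returned as tibbles
    with broom-style tidiers and ggplot2 plotting methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
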