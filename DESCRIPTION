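Package: nrbilayer
Title: Neutron Reflectometry and QCM-D Analysis of Supported Lipid
    Bilayers with Guest Molecules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Locates and quantifies a small guest molecule (such as
    caffeine) inside a solid-supported phospholipid bilayer from
    multi-contrast specular neutron reflectometry.  Provides scattering
    length density arithmetic from molecular formulas and volumes,
    slab-model construction with molecular constraints for supported
    bilayers, an exact Parratt reflectivity kernel with Nevot-Croce
    roughness and Gaussian resolution smearing, simultaneous
    co-refinement of several isotopic-contrast curves with chi-square
    profiling of parameter uncertainties, conversion of fitted slab
    parameters into guest volume fraction, mole percent and
    lipids-per-guest, component-group volume-fraction profiles, and
    Sauerbrey analysis of quartz-crystal microbalance with dissipation
    (QCM-D) traces.  A synthetic-data generator emulates multi-contrast
    reflectivity curves and QCM-D vesicle-fusion traces from known
    ground truth so every stage of the pipeline is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
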