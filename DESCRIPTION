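Package: crusparks
Title: Stochastic Spatial Simulation of Calcium Sparks in Ryanodine
    Receptor Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates elementary calcium release events (sparks) from a
    single cardiac calcium release unit. Free calcium and its buffers
    diffuse on a voxelized three-dimensional domain comprising cytosol,
    junctional and network sarcoplasmic reticulum (SR); the two domains
    are coupled through stochastically gating ryanodine receptor (RyR)
    channels with calcium-dependent two-state kinetics and through a
    three-state SERCA pump flux. Ships generators for compact and
    dispersed RyR cluster layouts, spatial phosphorylation patterns
    (inner, outer, uniform, blanket) selected by a principal-component
    ellipse criterion, fluorescence read-out with an optional Gaussian
    point-spread function, spark summary statistics (fidelity with
    Agresti-Coull intervals, amplitude, time to peak, duration), and a
    batch runner for geometry-by-phosphorylation experiment matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
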