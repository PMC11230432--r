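Package: nucgrowth
Title: Nuclear Growth Trajectory Analysis for hiPSC Colony Timelapse Imaging
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing multi-day timelapse measurements of nuclear
    size in human induced pluripotent stem cell (hiPSC) colonies. Provides
    frame-to-frame nucleus tracking by minimum-cost assignment with gap
    closing, automated trajectory quality control, detection of the
    transition from rapid post-mitotic nuclear expansion to slow growth,
    power-law growth-shape fitting, transient growth rates, Voronoi-based
    colony-context metrics (local density, normalized distance from colony
    center, radial height gradients, colony-time alignment), adder-model
    population statistics with bootstrap confidence intervals, lineage
    inheritance analysis with matched spatiotemporal control pairs, and
    bright-field colony-area measurement. A synthetic colony simulator with
    known ground truth exercises every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
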