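Package: beepath
Title: Langevin Walkers, Stop-and-Flight Segmentation and Utilization
    Density for Attraction-Driven Pedestrian Mobility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling and analysing pedestrian movement in open
    spaces structured by points of attraction. Provides an overdamped
    Langevin simulator with Von Mises turning (random walk, correlated,
    potential-driven and correlated potential-driven variants) over a
    landscape of gravitational-like attraction wells with trapping and
    visit memory; GPS track input (CSV/GPX) with local planar projection;
    stop-and-flight track segmentation by distance flagging and
    rectangular corridor grouping; movement statistics including
    two-timescale exponential stop-duration mixture fits, shifted
    exponential flight-length fits, orientation and velocity summaries and
    an active/reactive work decomposition; a simplified dynamic Brownian
    bridge utilization-density raster with isopleths; and a synthetic GPS
    data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    xml2
LinkingTo:
    Rcpp
Suggests:
    geosphere,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
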