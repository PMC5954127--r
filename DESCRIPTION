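Package: schoolsense
Title: Collective Gradient Sensing in Simulated Fish Schools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how schooling fish balance social information
    against individually sensed environmental gradients. Generates dynamic
    noisy light-field stimuli (a moving Gaussian dark spot over spatiotemporal
    background noise), simulates schools of self-propelled agents that combine
    zonal (repulsion/orientation/attraction) social interactions with a
    weighted gradient-sensing term and light-dependent speed modulation, and
    computes the associated group-level statistics: gradient-tracking
    performance, nearest-neighbour distance, group area and density, and
    binned correlations between individual accelerations and social or
    environmental cue vectors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
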