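Package: cytopattern
Title: Stochastic Simulation of Cytoneme- and Diffusion-Mediated Morphogen
    Patterning in Expanding Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based Monte-Carlo simulation of Wnt morphogen gradient
    formation and anteroposterior fate patterning in a rapidly expanding
    two-dimensional cell field, modelled on the zebrafish neural plate.
    Morphogen is delivered either by stochastic cytoneme (signaling
    filopodium) contacts or by an advection-dilution-diffusion equation on
    an exponentially growing domain; tissue dynamics include cell insertion
    (division and intercalation), random and gradient-directed neighbour
    swapping, and morphogen-discrepancy apoptosis. Cell fates are assigned
    by French-flag thresholds that split the population into thirds, and
    the package computes the associated pattern-quality and timing metrics
    (neighbourhood composition, threshold time-courses, fate-adoption
    tracing, boundary positions, neighbour lifetimes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    grDevices,
    graphics,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
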