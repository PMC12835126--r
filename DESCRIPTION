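Package: dualobserver
Title: Dual Observer Model of Spike-Sorting Efficiency for Electrode Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts the yield of well-isolated single units from
    extracellular electrode arrays using the dual observer model, in which
    each microelectrode observes a sphere of tissue of radius R and tissue
    seen by two or more electrodes contributes with a cooperation gain G.
    Provides exact inclusion-exclusion volumes for linear arrays, a seeded
    Monte-Carlo volume estimator for arbitrary (e.g. zig-zag) layouts, the
    closed-form optimal inter-electrode distance, a grid-search fit of
    (R, G, p_single) to units-per-channel measurements by cosine
    similarity, probe-layout construction and spatial downsampling, and a
    synthetic units-per-channel data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    graphics,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
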