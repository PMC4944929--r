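Package: retinaflow
Title: Flow-Based Network Analysis of Retinal Connectome Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds weighted synaptic graphs from electron-microscopy
    cell-to-cell contact lists (area filtering, per-pair aggregation and
    over-counting correction), computes centrality and shortest-path
    statistics, decomposes the network into modules by signal flow (a
    two-level map-equation / InfoMap search authored here) and by structural
    modularity methods, quantifies sample-excision edge artifacts and module
    mosaic geometry in the retinal plane, lays graphs out by classical
    scaling of geodesic distances, and extracts candidate circuits around
    high-flow neurons. A synthetic-data generator produces retina-like
    samples with known ground truth so every pipeline stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    ggplot2,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
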