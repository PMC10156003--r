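Package: abmcal
Title: Calibrating Spatial Agent-Based Tumor Models to Images with Learned
    Representations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating parameters of stochastic, center-based
    agent-based models (ABMs) of tumor-immune dynamics from spatial imaging
    data. Both ABM snapshots and image-derived cell tables are reduced to
    coarse multi-channel "simplified images", embedded into two dimensions by
    an ensemble of contrastively trained convolutional networks (SimCLR-style
    NT-Xent objective), and the ensemble-averaged embedding distance between a
    simulation and a target image is minimized with a genetic algorithm.
    Includes two example ABM variants (PD-L1 mediated T-cell suppression;
    hypoxic core with persistent dead cells), the image-processing pipeline
    (rasterize, crop, area-interpolated downsampling), Monte Carlo training-set
    generation, nearest-neighbor parameter-bound narrowing, and synthetic
    fixture generators for end-to-end self-fit experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
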