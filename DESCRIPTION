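Package: vesseltex
Title: Texture-Based Preprocessing and Topology-Aware Evaluation for
    Time-Sequential Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for vessel-focused preprocessing of time-sequential
    digital subtraction angiography (DSA): local-contrast, local-entropy
    and brightness-percentile texture descriptors fused into a combined
    vessel-evidence map, minimum-intensity-projection model inputs, and a
    CLAHE baseline. Includes pixel-overlap segmentation metrics, a
    skeleton-based Vessel Connectivity metric that penalises fragmented
    centerlines, a synthetic vascular phantom generator with exact ground
    truth and controlled mask degradations, patch tiling/stitching and
    augmentation utilities, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    png,
    tiff,
    yaml,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
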