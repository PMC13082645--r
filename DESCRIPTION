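Package: lineagetrack
Title: Single-Cell Tracking, Lineage Reconstruction and Fate Analysis for
    Time-Lapse Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for time-lapse fluorescence
    videomicroscopy of adherent cells: image pre-processing, per-frame
    segmentation with a pluggable backend, overlap-based frame-to-frame
    tracking with optimal bipartite assignment, mitosis detection and
    lineage-tree reconstruction, radiation-response fate classification
    (proliferative, transiently arrested, long-term arrested), and
    single-cell bioparameters (exponential growth and doubling time,
    MSD-based diffusion coefficients, surface-area dynamics,
    probability-to-exceed curves with bootstrap errors on the median).
    Includes a synthetic-movie simulator with exact ground-truth masks and
    lineages, and HOTA-style tracking-quality metrics (detection accuracy,
    association accuracy, lineage assignment, division detection, lifetime
    agreement) for validating the pipeline without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
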