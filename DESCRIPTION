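Package: svfusion
Title: Single-Vesicle Supported-Membrane Fusion Assay Simulation and Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and kinetic analysis of single-vesicle fusion assays
    in which secretory vesicles dock to and fuse with a planar-supported
    bilayer under TIRF illumination. Generates synthetic movies and intensity
    traces with the characteristic line shapes of docking, fusion-pore
    opening and vesicle collapse for protein-cargo and small-dye labels;
    implements the moving-average / maximum-projection / spot-detection /
    ROI-trace image-analysis chain; times docking, fusion and calcium
    arrival; and fits single-exponential and sequential-step delay-time
    kinetics with right censoring, bootstrap intervals, and the log-linear
    relation between fusion rate and membrane curvature.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
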