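Package: slicetracks
Title: Immune-Cell Migration Analysis in Tumor Slice and Matrigel Microscopy
Version: 0.1.0
Authors@R:
    person("Slice", "Tracks Developers", email = "slicetracks@example.org",
           role = c("aut", "cre"))
Description: Quantifies immune-cell migration in two-compartment (tumor islet
    versus extracellular-matrix stroma) multichannel time-lapse confocal
    stacks of living tumor slices, and 3D invasion distances in Matrigel
    Z-stacks. Provides sample-drift correction from the matrix channel,
    bleed-through and background correction, intensity-based cell
    segmentation with size filtering and Z-collapse, frame-to-frame track
    linking with gap closing and rule-based track merging, momentary-speed
    and tumor-dwell metrics, 3D watershed nuclei segmentation with
    percentile-baseline invasion distances, and closed-form cytotoxicity
    and caliper tumor-volume formulas. A synthetic-scene generator with
    exported ground truth makes every stage testable without raw microscopy
    data.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
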