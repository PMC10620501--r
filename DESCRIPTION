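Package: azlmquant
Title: Quantification of Endocytosed Synaptophysin-pHluorin Around
    Active-Zone-Like Membranes in TIRF Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying stimulus-evoked exocytosis and
    endocytosis of synaptophysin tagged with super-ecliptic pHluorin
    (Syp-SEP) around active-zone-like membranes (AZLM) imaged by total
    internal reflection fluorescence microscopy with rapid extracellular
    pH exchange. Implements the full measurement chain (stage-drift
    compensation, double-exponential photobleach correction,
    mean-plus-k-SD background thresholding, area-gated segmentation with
    watershed splitting, pH 6.0 window averaging and pre-stimulus
    subtraction, intensity centroids, signed distances to the AZLM edge,
    trial-to-trial displacement, and time-course statistics), the three
    instrument calibrations (single-molecule step-bleach intensity,
    evanescent-field decay length, solution-exchange time), and a seeded
    synthetic acquisition simulator with full ground truth so that every
    stage can be validated without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
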