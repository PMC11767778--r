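Package: rbcflow
Title: Image Flow Analysis of Red Blood Cell Aggregation in Microfluidic Channels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies red blood cell (RBC) aggregation from phase-contrast
    microscopy images of microfluidic flow channels. Segments RBC aggregates by
    global thresholding, boundary refinement and connected-component particle
    analysis, stratifies detected particles into six area-defined populations
    (single cells P0 through large three-dimensional cluster networks P5),
    computes per-field Aggregation-Area Indicators (AAI) and aggregate counts
    (NA) for each population, renders color-coded overlays, and compares study
    groups with Shapiro-Wilk screening and exact Wilcoxon rank-sum tests.
    Includes analytic hemorheology conversions (wall shear stress to shear
    rate, dilution hematocrit) and a seeded synthetic-field generator that
    emulates single cells, linear rouleaux and compact 3-D clusters with exact
    per-object ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    tiff,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
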