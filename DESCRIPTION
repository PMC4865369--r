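Package: plangrad
Title: Quantification of Body-Wide Expression Gradients and Trunk
    Patterning Phenotypes in Planarians
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify anteroposterior expression gradients and
    trunk-patterning phenotypes in whole-mount planarian images.
    Implements axis-normalized intensity profiling of colorimetric in
    situ hybridization stains, triple-FISH cell segmentation by minimum
    cross-entropy (Li) auto-thresholding with particle filtering on
    physical area and circularity, eight-state high/low co-expression
    classification with threshold-sweep robustness checks, RNAi-screen
    statistics (exact 2x2 tests with Benjamini-Hochberg correction),
    organ-position and domain-size morphometrics, and delta-delta-Ct
    qPCR summaries. A synthetic-worm generator renders seeded WISH- and
    FISH-like images with per-cell ground truth so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    EBImage,
    tiff,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
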