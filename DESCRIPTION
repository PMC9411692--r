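Package: cranioview
Title: Vertex-View Cranial Measurement for Positional Skull Deformities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies positional plagiocephaly and brachycephaly from a
    two-dimensional vertex-view head contour and three anatomical landmarks
    (nasal dorsum and both anterior helical borders of the ears). Constructs
    the mediolateral and anteroposterior measurement frame, measures oblique
    skull-chord diagonals, and computes the cranial vault asymmetry index
    (CVAI, 30 degrees), cranial index (CI), and digitally emulated
    plagiocephalometry indices ODDI (40 degrees) and CPI. Includes ordinal
    severity classification on the published cut-off scales (with the 5-to-4
    level CVAI scale reduction), method-comparison statistics
    (cross-tabulation with exact and off-by-one match proportions, Pearson
    correlation, Mann-Whitney U), a parametric synthetic skull generator with
    independent ground-truth oracles, mask-to-contour extraction, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    png,
    EBImage,
    stats,
    grDevices,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
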