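Package: cephalo
Title: Photogrammetric Head Circumference Measurement and Agreement Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale toolkit for estimating occipitofrontal head
    circumference (HC) from a single photograph containing a head-like oval
    region and a circular reference object of known physical diameter.
    Provides the measurement pipeline (foreground segmentation, direct
    least-squares ellipse fitting, four-point manual landmark fusion,
    reference-object scale calibration, Ramanujan perimeter), a synthetic
    phantom renderer and rater-study simulator with exact ground truth, and
    the method-comparison statistics used to validate such instruments:
    two-way random-effects intraclass correlation with interpretation bands,
    Bland-Altman limits of agreement, binned Cohen kappa, standard error of
    measurement, variance-ratio and two-sample t tests, Shapiro-Wilk
    normality checks and survey summaries. A command-line interface ties the
    pieces into a reproducible workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    EBImage,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Software, Visualization
RoxygenNote: 7.3.3
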