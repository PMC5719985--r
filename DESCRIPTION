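Package: pharmacoscopy
Title: Image-Based Ex Vivo Drug Response Profiling for Haematological Malignancies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for image-based ex vivo drug sensitivity
    screening (pharmacoscopy) of primary patient samples in 384-well plates.
    Computes relative blast fractions (RBF) from single-cell derived well
    counts, normalises them into pharmacoscopy scores, ranks drugs and tests
    per-drug significance, integrates scores over administered regimens
    (i-PCY), classifies clinical response with an AUROC-weighted per-point
    decision surface under leave-k-out cross-validation, and analyses clinical
    endpoints (Kaplan-Meier, log-rank, McNemar, odds ratios, PFS ratios).
    Includes a synthetic-data generator for well counts, patient cohorts and
    clinical outcomes, and a simplified two-channel fluorescence image
    simulation and segmentation stage that derives viable marker-positive and
    marker-negative cell counts from nuclear morphology.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    survival,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
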