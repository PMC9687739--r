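Package: mammocad
Title: Mammogram Lesion Segmentation and Ensemble Classification Pipeline
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end computer-aided-diagnosis pipeline for craniocaudal-view
    mammograms: artefact removal (border masking, largest-contour breast isolation,
    Canny/Hough vertical-line removal), contrast enhancement (gamma correction and
    contrast-limited adaptive histogram equalisation), image-quality verification
    (MSE, RMSE, PSNR, SSIM), sevenfold geometric augmentation, seeded region-growing
    lesion segmentation with a per-image dynamic intensity threshold, sixteen
    geometric/intensity/texture descriptors per lesion, and an accuracy-thresholded
    stacking ensemble over an eleven-member classifier bank with five feature-selection
    strategies and a K-fold robustness sweep. A seeded synthetic phantom generator
    provides ground-truth breast, lesion and artefact masks so the whole pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    glmnet,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'RcppExports.R'
    'accessors.R'
    'augment.R'
    'roi.R'
    'features.R'
    'learners.R'
    'ensemble.R'
    'mammocad-package.R'
    'phantom.R'
    'pipeline.R'
    'preprocess.R'
    'quality.R'
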