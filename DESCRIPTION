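Package: deepclahe
Title: Neural-Network-Optimized Hounsfield-Unit Transformation and CLAHE
    Enhancement for Ischemic-Stroke CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for temporal-stage-specific enhancement of non-contrast brain
    CT. A compact convolutional network predicts, per scan, the slope and
    intercept of a linear Hounsfield-unit transformation together with a CLAHE
    clip limit, trained to minimize a composite objective that rewards
    block-based contrast (EME) while preserving fidelity to the windowed
    original (PSNR) under a parameter-range penalty. Includes a seeded
    stage-labeled synthetic CT phantom generator with ground-truth lesion
    masks, the HU preprocessing pipeline (rescale, resample, window, 8-bit
    quantization), contrast-limited adaptive histogram equalization and six
    classical enhancers, an exhaustive per-image grid-search optimizer used as
    a verification oracle, paired t-test comparison harnesses, downstream
    stage classification with stratified cross-validation, and Grad-CAM
    attention maps with a lesion localization score.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    png,
    glmnet,
    e1071,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    optparse
Config/testthat/edition: 3
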