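Package: mffcnet
Title: Multi-Modal MRI Feature-Fusion Classification of Brain Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Three-class brain-tumor classification (glioblastoma, solitary
    brain metastasis, primary CNS lymphoma) from co-registered CE-T1WI and
    T2-Flair MRI. Implements parallel DenseBlock encoders, an L1-norm
    activity-map feature-fusion layer, spatial-channel attention, a softmax
    decoder trained with Adam, patient-level slice averaging, stratified
    patient-level cross-validation, ROC cutoff and classification metrics,
    and Grad-CAM explanation maps. Includes a standardized preprocessing
    chain for NIfTI volumes (resampling to a reference grid, mean +/- 3 sd
    intensity windowing, square brain cropping, 240x240 rescaling with
    [0, 255] normalization) and a seeded synthetic phantom generator that
    emulates the three lesion phenotypes so the full pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    png
Config/testthat/edition: 3
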