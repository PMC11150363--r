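Package: brainage
Title: Brain Age Estimation from Structural MRI with an Attention-Augmented 3D Residual Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates brain age from T1-weighted structural MRI volumes with a 3D
    residual convolutional network interleaved with self-attention blocks, fuses
    subject sex into the learned representation, and refines the prediction with a
    support-vector-regression head on the penultimate features. The brain-age gap
    (predicted minus chronological age) is then used as a single biomarker for
    Alzheimer's-versus-normal classification by an ensemble of four classifiers
    combined by majority voting. Includes a preprocessing chain (brain extraction,
    multiplicative bias-field correction, resampling, intensity normalisation), a
    synthetic age-encoded phantom generator so the whole pipeline is testable
    without clinical data, Grad-CAM volumetric saliency maps, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    e1071,
    xgboost,
    rpart,
    MASS,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
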