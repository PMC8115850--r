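Package: osteoage
Title: Automated Skeletal Age Estimation from 3D CT of the Mandible and Femur
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for forensic age estimation from 3D computed
    tomography. Reads axial CT series in DICOM format, converts stored pixel
    values to Hounsfield units, resamples volumes to isotropic resolution,
    segments cortical bone of the femur by intensity windowing and extracts the
    mandible by per-slice thresholding, morphological opening and
    connected-component filtering. Fixed-shape bone voxels feed 3D
    convolutional network regressors (ResNet-34/50 style basic and bottleneck
    residual blocks, plus MobileNet and SqueezeNet style variants) with a
    binary-sex embedding branch and early, middle, and late multimodal fusion.
    Includes a synthetic CT-phantom cohort generator with a parameterized
    age signal in bone density and cortical thickness, a seeded training loop
    (Adam, plateau learning-rate schedule, random-crop augmentation,
    progressive input-size transfer), stratified k-fold cross-validation, and
    agreement metrics (MAE, Pearson correlation, Lin's concordance
    correlation coefficient).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
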