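Package: gaborenc
Title: Region-Based Visual Encoding of fMRI Voxel Responses with Learnable Gabor Convolutions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end visual encoding of fMRI voxel responses from grayscale
    natural-image stimuli. The encoder is a lightweight four-layer network whose
    first layer is a bank of parametric Gabor kernels (spatial frequency,
    envelope width, phase, orientation) that remain learnable during training;
    two regular convolutional layers and a squared-weight fully connected map
    predict all voxels of one region of interest jointly. Training uses a
    correlation-weighted loss with noise regularisation and adaptive moment
    estimation. The package also provides permutation-based significance
    thresholds for prediction accuracy, pairwise model dominance tests, guided
    backpropagation for receptive-field estimation and preferred-kernel
    ranking, Mann-Kendall trend statistics across cortical areas, and a
    synthetic-data generator with known ground-truth voxel tuning for
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
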