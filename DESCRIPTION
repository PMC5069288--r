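Package: wedag
Title: Wavelet-Entropy Features and DAG-SVM Classification of Brain Image Slices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computer-aided classification of 2D brain image slices into
    healthy controls and left- or right-sided sensorineural hearing loss.
    Implements the biorthogonal 2D discrete wavelet transform (bior5.5),
    wavelet-entropy feature extraction (one Shannon entropy per subband of an
    n-level decomposition), a soft-margin linear support vector machine
    trained by sequential minimal optimization, and a decision directed
    acyclic graph (DDAG) multiclass wrapper.  Includes a repeated stratified
    k-fold cross-validation harness with confusion-matrix aggregation and
    per-class sensitivity, specificity, precision and accuracy, a synthetic
    brain-slice phantom generator for end-to-end testing, and file-format
    plumbing (PNG, NIfTI, CSV, JSON) with a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    RNifti,
    stats,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
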