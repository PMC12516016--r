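Package: wavefrac
Title: Multiband Wavelet-Subband Deep Representation Learning for
    Fracture Radiograph Classification
Version: 0.1.0
Authors@R:
    person("Radiograph", "Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Binary fracture / non-fracture classification of long-bone
    radiographs through multiband frequency decomposition.  Each image is
    split into four full-size subband image tensors (LL, LH, HL, HH) by a
    one-level 2D discrete wavelet transform with per-subband inverse
    reconstruction (stationary-wavelet and SVD eigentriple-grouping
    alternatives are provided).  A frozen convolutional backbone plus a
    trainable dense - batch-normalisation - dropout head scores each
    subband; the per-subband probability vector is fused by a dense layer
    into the final decision.  Includes stratified hold-out and k-fold
    evaluation (accuracy, precision, recall, F1, Cohen's kappa, AUROC,
    AUPRC), per-subband Grad-CAM saliency maps, a synthetic long-bone
    image generator for download-free end-to-end exercise, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jpeg,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
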