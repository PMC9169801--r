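Package: rightreasons
Title: Explanation-Guided Training of Leaf-Image Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains small convolutional image classifiers for plant-leaf
    tasks, explains them with gradient-weighted class activation mapping
    (Grad-CAM), encodes domain expertise as automatically generated binary
    annotation matrices, and retrains with a balanced right-for-the-right-
    reasons (RRR) input-gradient penalty so the model attends to
    task-relevant pixels.  Ships a synthetic leaf-scene simulator with exact
    ground-truth masks (transparent-circle lesions, background and
    bounding-rectangle annotations), explanation-assessment metrics (RMSE,
    cosine similarity, proportion of important pixels), an end-to-end
    baseline-versus-RRR comparison pipeline, and a k-fold cross-validation
    harness.  The network engine (convolution, pooling, softmax
    cross-entropy, Adam) including the double-backpropagation pass that
    differentiates the input-gradient penalty with respect to the weights is
    implemented in base R for full determinism and inspectability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
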