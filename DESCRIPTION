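Package: dermacaps
Title: Dermoscopy Lesion Analysis with Active-Contour Segmentation and
    Attention-Guided Capsule Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for dermoscopy skin-lesion images:
    a synthetic lesion-image generator with analytic ground truth,
    intensity normalization and augmentation preprocessing with image
    quality and class-assessment reports, active-contour (snake)
    segmentation driven by a diffused edge force field with hair
    detection and inpainting, handcrafted border and color descriptors
    (convexity, circularity, irregularity index), a residual
    convolutional backbone with CBAM channel/spatial attention, and a
    matrix-capsule classification head with inverted dot-product
    attention routing, trained by minibatch stochastic gradient descent.
    All components run on CPU with images produced by the built-in
    generator; no external data are required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    cluster,
    grDevices,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
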