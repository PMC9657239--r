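Package: freqshot
Title: Frequency-Domain Few-Shot Learning for Plant Disease Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Few-shot recognition of plant-disease images in the frequency
    domain. Converts RGB leaf images to a JPEG-style YCbCr 4:2:0 block-DCT
    representation, selects informative frequency channels either by fixed
    low-frequency rules or by squeeze-and-excitation attention weights,
    calibrates encoder feature vectors toward a Gaussian-like distribution
    (vertical slide, Tukey power transform, Euclidean normalization,
    centralization), and classifies query images in N-way/K-shot episodes by
    cosine similarity to class centroids. Includes lightweight convolutional
    encoders with an image-wise pre-training stage, synthetic leaf-image and
    feature-cluster generators for desk-scale experiments, and tidy
    evaluation summaries.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    EBImage
Suggests:
    yaml,
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
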