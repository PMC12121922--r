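Package: thermocad
Title: Computer-Aided Diagnosis of Breast Thermograms with Texture and Chaotic Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A pipeline for computer-aided analysis of infrared breast
    thermograms. Segments the hottest region of a thermal image with Otsu
    thresholding, HSI pseudo-coloring and fuzzy c-means clustering, extracts
    gray-level co-occurrence (Haralick-style) texture descriptors and
    nonlinear complexity indices (box-counting fractal dimension, largest
    Lyapunov exponent, Kolmogorov-Sinai entropy, correlation dimension),
    selects discriminative features with the multi-objective NSGA-III
    algorithm (with GA, PSO and differential-evolution baselines), and
    evaluates benign-versus-malignant classification with five classifiers
    under stratified 10-fold cross-validation. Includes seeded phantom
    generators so every stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    class,
    e1071,
    MASS,
    png,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
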