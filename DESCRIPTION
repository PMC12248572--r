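Package: octmf
Title: Multifractal Box-Counting Analysis and Classification of Retinal OCT Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for texture-based screening of retinal optical coherence
    tomography (OCT) scans using multifractal geometry. Implements an image
    conditioning pipeline (Gaussian blur, contrast-limited adaptive histogram
    equalization, Otsu binarization), 2D box-counting estimation of the
    generalized dimensions D(q) and the Legendre singularity spectrum f(alpha)
    with its clinical landmark descriptors, and stratified k-fold evaluation of
    a panel of classifiers (including a two-hidden-layer perceptron trained
    with Adam) on the resulting nine-descriptor feature tables. A synthetic
    module provides canonical fractals with closed-form spectra (Sierpinski
    carpet, two-dimensional binomial cascades) and layered two-class retinal
    phantoms, so every stage of the pipeline can be validated against
    analytically known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    utils,
    e1071,
    randomForest,
    rpart,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
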