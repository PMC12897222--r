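Package: grainspec
Title: Hyperspectral Detection of Hidden Insect Infestation in Grain Kernels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A chemometrics pipeline for nondestructive detection of hidden
    stored-grain pest infestation (e.g. rice weevil immature stages inside
    wheat kernels) from near-infrared hyperspectral images. Provides ENVI
    hypercube input/output with black-and-white reflectance correction and
    single-kernel mean-spectrum extraction; seven spectral preprocessing
    transforms (Savitzky-Golay smoothing and derivatives, multiplicative
    scatter correction, standard normal variate, detrending, asymmetric
    least-squares baseline correction); a partial least squares engine with
    cross-validated RMSECV; four PLS-driven wavelength-selection algorithms
    (CARS, SPA, UVE, IRIV) and their SPA-chained combinations; Kennard-Stone
    sample partitioning; SVM, decision-tree, k-nearest-neighbour and
    random-forest classifiers with grid-search tuning; confusion-matrix
    evaluation (accuracy, precision, recall, F1, Cohen's kappa); and a
    synthetic spectra/cube generator with planted discriminative wavelength
    windows for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Matrix,
    e1071,
    rpart,
    class,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    signal,
    mixOmics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
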