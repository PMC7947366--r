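Package: t2nomo
Title: Volumetric T2 Relaxometry Histogram Features and Nomogram
    Modelling of Treatment Response in Thyroid-Associated Ophthalmopathy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting the response of thyroid-associated
    ophthalmopathy (TAO) to intravenous methylprednisolone from orbital
    multi-echo MRI. Provides voxel-wise mono-exponential T2 relaxometry,
    first-order T2-relaxation-time histogram features of extraocular-muscle
    volumes of interest (percentiles, skewness, kurtosis, entropy,
    inhomogeneity), Youden-index cutoff selection with DeLong confidence
    intervals, chi-squared univariate screening, binary logistic regression
    with a points-based nomogram and concordance index, and a synthetic
    multi-echo phantom generator with Rician noise so that the whole
    pipeline is testable without patient data. Includes NIfTI-1 input and
    output and an end-to-end reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    minpack.lm,
    graphics,
    stats,
    tools,
    utils
Suggests:
    withr,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
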