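Package: calcrsa
Title: Representational Analyses of Approximate Mental Calculation fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to study how internally generated results of approximate
    non-symbolic calculation are represented in multi-voxel fMRI patterns.
    Implements the 10-condition multiply/divide design on numerosities
    {6, 12, 24, 48} with its four predictor dissimilarity matrices (sample,
    operation, operand, result), a finite-impulse-response GLM for
    time-resolved response estimation, representational-similarity regression
    of neural dissimilarity matrices on the predictors (region-of-interest
    and volumetric searchlight), cross-temporal support-vector-regression
    decoding of numerosity between sample and result codes, psychometric
    estimation of behavioral precision (Weber fraction, JND, PSE), and
    group-level inference (one-sample tests, Benjamini-Hochberg FDR,
    sign-flip cluster permutation, brain-behavior correlation). A synthetic
    BOLD and behavior generator with known embedded codes makes every stage
    testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
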