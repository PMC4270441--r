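Package: kernelrep
Title: Kernel Analysis and Noise-Matched Comparison of Neural and Model Representations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing the representational performance of neural
    populations and model feature spaces on invariant object categorization
    tasks. Implements kernel analysis: Gaussian-kernel ridge regression with
    closed-form leave-one-out error, yielding precision versus complexity
    curves and an area-under-the-curve summary, with bootstrap resampling
    over category-balanced image subsets. Provides sample- and noise-matched
    correction of model representations via a rate-dependent (Poisson-like)
    additive Gaussian noise model estimated from trial-structured recordings,
    cross-validated linear support-vector decoding, ridge encoding models
    with explainable-variance normalization, object-level representational
    dissimilarity matrices and their Spearman comparison, and a synthetic
    generator of stimulus sets, latent representations and trial tensors for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
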