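Package: spotglow
Title: Background Correction, Glog Transformation and Preprocessing
    Assessment for Spotted Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Preprocessing of one-color spotted microarray spot tables:
    four background-correction methods (standard subtraction, no
    background, the Edwards smooth-monotone correction and the
    normal-plus-exponential convolution model), log2 and generalized-log
    (glog) transformations with maximum-likelihood parameter estimation,
    global-median normalization, replicate-spot averaging and
    empirical-Bayes moderated t-statistics, plus a hybrid transformation
    that takes fold-changes from the log2 pipeline and p-values from the
    glog pipeline.  Includes the evaluation machinery needed to compare
    preprocessing choices against a low-noise gold standard (fold-change
    compression curves, SD-versus-intensity curves, Pearson and
    intraclass-correlation concordance, probit-scale p-value concordance,
    volcano classification with confusion metrics), a test of the
    additive-background hypothesis from replicate-spot regressions, and a
    seeded synthetic-data generator emulating spatially structured
    background and two-component measurement error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    limma,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
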