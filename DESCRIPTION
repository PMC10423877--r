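Package: crossdecomp
Title: Comparing Canonical Correlation and Partial Least Squares
    Decompositions of Two-Block Data
Version: 0.1.0
Authors@R: person("BRAINS", "Lab", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits and compares the three cross-decomposition methods most
    used in brain-behavior research - canonical correlation analysis (CCA),
    partial least squares correlation (PLSC) and partial least squares
    regression (PLSR) - on two blocks of variables measured on the same
    samples.  Provides confound residualization and standardization,
    variance-inflation diagnostics, permutation testing of latent
    components, structure coefficients (loadings), explained variance, a
    quantitative cross-method component-alignment report, and a synthetic
    two-block generator with planted low-rank signal and ground truth for
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
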