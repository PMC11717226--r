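Package: varxGranger
Title: VARX Granger Analysis of Endogenous Dynamics and Exogenous Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint estimation of delayed endogenous (autoregressive) and
    exogenous (moving-average) effects in multivariate time series with a
    vector autoregressive model with exogenous input (VARX).  Per-channel
    Granger tests are computed as likelihood-ratio deviances with chi-square
    p-values and generalized R-squared effect sizes, including a de-biased
    deviance that corrects for L2 (ridge) regularization with effective
    sample size T' = T - N.  Supports Gaussian basis compression of long
    input filters, missing-value and multi-segment masking in the
    block-Toeplitz normal equations, equation-error and output-error
    simulators, factored impulse responses H = (I - A)^-1 B, and seeded
    simulation studies of parameter recovery, p-value calibration, and
    causal-structure failure modes (colliders, unobserved common causes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
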