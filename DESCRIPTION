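Package: quantalmoments
Title: Moment-Based Quantal Analysis of Evoked EPSC Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fast moment-based estimation of synaptic parameters from trains
    of evoked excitatory postsynaptic currents (EPSCs). Closed-form estimators
    of quantal size, effective vesicle pool size and stimulus-dependent
    release probability are obtained from per-stimulus means, variances and
    cross-stimulus covariances, with an explicit correction for sweep-level
    quantal variability. Includes Tsodyks-Markram short-term plasticity
    calibration of the pool size, a classical variance-mean baseline, a
    generative simulator of binomial vesicle release with facilitation
    dynamics, EPSC peak extraction from raw current traces, and a
    parameter-recovery harness for sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
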