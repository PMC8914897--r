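Package: hrvdvc
Title: Physiologically Constrained Filtering and Imputation of RR-Interval Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Preprocessing of ambulatory heart-rate-variability (HRV) recordings
    given as RR-interval time series. Implements the DVC
    (distribution-variability-characteristics) approach: ectopic intervals
    shorter than the physiological minimum are resolved by validated right/left
    merges that preserve the timestamp-interval equality, intervals above the
    physiological maximum are deleted, and the resulting gaps are filled
    backwards with Gaussian-sampled intervals fitted to the local signal.
    Also provides the standard interpolation baselines (linear, shape-preserving
    cubic, cubic spline, deletion), time/frequency/non-linear HRV feature
    extraction over sliding windows (SDNN, RMSSD, pNN50, LF/HF, Poincare
    SD1/SD2), a realistic RR-series simulator with a degradation protocol
    (random beat deletion plus ectopic injection), and a validation harness
    comparing reconstruction methods by downstream stress-classification F1.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    pracma,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
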