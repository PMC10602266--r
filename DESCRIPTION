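Package: ifpulse
Title: Intrinsic Frequency Analysis of Arterial Pressure Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for intrinsic frequency (IF) analysis of single-cycle
    arterial pressure waveforms. Implements the dimensionless standard form
    (min-max amplitude normalization, unit cardiac cycle, 500-sample cubic
    spline resampling), the constrained piecewise-sinusoid L2 solver that
    extracts systolic and diastolic intrinsic frequencies under continuity
    and periodicity constraints, a synthetic waveform generator with exact
    ground-truth parameters, a sequentially-reduced feedforward neural
    network surrogate that maps a waveform and its dicrotic notch time
    directly to scaled IF parameters, and agreement statistics (RMSE,
    relative errors, Pearson correlation, Bland-Altman) for comparing the
    surrogate against the optimization-based solver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
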