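Package: polyspike
Title: Spike-In Normalized Quantification for Polysome Profiling RT-qPCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantifies per-fraction RT-qPCR signal from polysome profiling
    experiments that use a cross-species total-RNA spike-in (e.g. yeast RLP24)
    added in equal amount to every sucrose-gradient fraction. Converts
    quantification cycles (Cq) to relative quantities, normalizes them to the
    spike-in reference to cancel per-fraction RNA-isolation losses, expresses
    each transcript's distribution as percentage signal over an analysis
    window, and summarises translational shifts with the signal-weighted mean
    fraction number F_W and its treatment difference dF_W, with one-tailed
    paired t-tests and a pairing-effectiveness correlation diagnostic. Includes
    a seeded generator of synthetic Cq tables with known fraction
    distributions, treatment shifts and per-fraction loss factors for
    validating the normalization.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
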