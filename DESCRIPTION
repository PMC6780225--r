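Package: fndtrace
Title: Background-Free Quantification of Fluorescent Nanodiamond-Labeled Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative pipeline for long-term tracking of cells labeled with
    fluorescent nanodiamonds (FNDs). Implements magnetically modulated
    fluorescence (MMF) demodulation by FFT lock-in at the field-modulation
    frequency, calibration-curve quantification with limit-of-detection
    estimation, conversion of recovered FND mass to particle counts and
    per-cell loading, lifetime-based time gating of photon arrival histograms
    for autofluorescence rejection, and field-based microscopy quantification
    (nucleus counting, FND-positive cell detection, Manders colocalization).
    Ships forward simulators for every input (modulated emission spectra,
    photon-decay histograms and stacks, multichannel histology fields) with
    recorded ground truth, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    yaml,
    tiff,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    jsonlite
Config/testthat/edition: 3
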