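Package: erdentropy
Title: Spectral Entropy Analysis of Movement-Related EEG Desynchronization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sensor-level analysis of movement-related oscillatory power in
    multichannel EEG. Estimates single-Hanning-taper spectral power on a 1-Hz
    grid from 8 to 25 Hz, expresses movement power as percent change relative
    to a resting baseline, and summarises the shape of the resulting spectrum
    with a normalized spectral entropy that separates broadband
    ("aged-like") from narrowband ("young-like") desynchronization.
    Includes a seeded synthetic-EEG generator with group- and task-specific
    modulation profiles, channel-wise two-group tests with
    Benjamini-Hochberg false-discovery-rate control, per-channel
    random-intercept linear mixed models with post-hoc task contrasts via
    estimated marginal means, an end-to-end pipeline with reproducible
    TSV/JSON outputs, and minimal EDF import/export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
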