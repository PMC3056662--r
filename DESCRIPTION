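Package: sonarpam
Title: Passive Acoustic Monitoring Analysis of Beaked Whale Responses to Sonar
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying behavioral responses of deep-diving
    odontocetes to naval sonar from passive acoustic monitoring and
    biologging data. Detects group clicking periods (GCPs) on bottom-mounted
    hydrophone arrays, summarizes foraging rates across exposure phases and
    tests them with Monte Carlo randomization, computes third-octave-band
    sound pressure levels and per-ping and cumulative sound exposure levels
    from calibrated tag pressure records, extracts per-dive response
    parameters from depth and acoustic-audit records, and speed-filters
    satellite location tracks. Includes synthetic-data generators that
    emulate the structure of range and tag data with ground truth retained,
    so the full pipeline is testable without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    graphics,
    grDevices,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
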