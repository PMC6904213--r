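Package: premacc
Title: Premature Evidence Accumulation Under Temporal Uncertainty
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for two-alternative perceptual
    decisions with temporally uncertain evidence onsets. Generates flickering
    overlaid-grating and random-dot-kinematogram stimulus streams, computes
    opponent (Adelson-Bergen) dot-motion energy and its pre-evidence
    integrals, simulates behaviour and 128-channel EEG from a variable-onset
    bounded accumulator, and measures the standard electrophysiological
    decision signals: frequency-tagged SSVEP signal-to-noise ratios,
    centro-parietal positivity amplitude and build-up rate, Mu/Beta
    lateralisation, and the bilateral N2, together with conditional accuracy
    functions, sequential-foreperiod summaries and repeated-measures ANOVA
    with Greenhouse-Geisser correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    signal,
    tibble,
    dplyr,
    tidyr,
    rlang,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    readr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
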