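Package: svdcfield
Title: Slow-Varying DC Field Analysis of Intracranial EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Band decomposition, energy-ratio statistics, active/stable
    phase detection, cross-lead dispersion onset analysis and
    correlation/phase-synchronization propagation analysis for
    multichannel intracranial EEG, built around the slow-varying
    direct-current (0.01-0.5 Hz) component of the signal. Includes a
    seeded phenomenological generator of annotated synthetic SEEG
    recordings with ground truth for validating every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
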