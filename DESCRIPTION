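Package: iurhythm
Title: Phase Consistency of Intonation Unit Onsets with the Speech Envelope
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the low-frequency rhythm of prosodic
    segmentation in spontaneous speech. Computes the wideband speech
    envelope through a cochlear-spaced filterbank with Hilbert magnitudes,
    estimates per-speaker pairwise phase consistency (PPC) spectra of
    Intonation Unit (IU) onsets relative to the envelope, assesses
    significance with a trough-constrained temporal permutation null and
    false-discovery-rate control across frequency bins, and summarizes IU
    duration distributions with bootstrap confidence intervals. Includes a
    synthetic conversation generator with known ground truth for validating
    the full pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
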