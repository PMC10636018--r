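Package: laminar
Title: Laminar Hippocampal Electrophysiology After Concussion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for laminar hippocampal CA1 recordings in a
    large-animal model of concussion. Provides single-unit metrics (firing
    rate, spike amplitude and width, autocorrelogram first moment), putative
    pyramidal/interneuron classification with a k-means cross-check,
    spike-LFP entrainment via the mean vector length over 1-300 Hz, Welch
    power spectral density with z-scored group comparison, detectors for
    hyperexcitability events (sustained depolarizing shifts and 6-8 Hz
    paroxysmal rhythmic spikes), a single-compartment fast-spiking
    parvalbumin-positive interneuron model with perturbable sodium-channel
    kinetics and window-current analysis, and a synthetic-data generator
    producing laminar LFP with phase-locked spike trains so the whole
    pipeline is testable without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
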