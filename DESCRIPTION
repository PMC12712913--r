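Package: sonolfp
Title: Local Field Potential Analysis for Sonogenetic Ultrasound Neuromodulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for extracellular local field potential (LFP)
    recordings from focused-ultrasound neuromodulation experiments with
    genetically targeted mechanosensitive channels. Provides recording
    containers and file I/O, a synthetic-session generator with group presets,
    the standard signal-cleaning chain (notch and zero-phase Butterworth
    bandpass filtering, template-based ultrasound-artifact rejection, epoching,
    baseline correction), Welch spectral estimation with canonical band powers
    and stimulation-normalized power change, per-trial ultrasound-evoked
    potential (N1) amplitude and latency quantification, ultrasound dosimetry
    (duty cycle, Ispta/Isppa, mechanical index, zero-dimensional bio-heat
    temperature estimation), behavioral scoring from event tables, and the
    Shapiro-Wilk gated ANOVA/Dunnett versus Kruskal-Wallis/Dunn group
    comparison battery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml,
    multcomp,
    car
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
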