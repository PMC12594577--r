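Package: codavowel
Title: Spectral Analysis of Sperm Whale Coda Vowels and Diphthongs
Version: 0.1.0
Authors@R: person("Coda", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An acoustic-analysis pipeline for identifying discrete
    vowel-like (a/i) and diphthong-like spectral patterns in sperm whale
    codas. Provides time-insensitive coda assembly from annotated click
    trains, per-click Welch spectra with constrained peak detection and
    majority/mismatch statistics, LPC formant tracking with
    smoothest-path candidate selection over a hyperparameter grid,
    Gaussian-mixture (BIC) tests of trajectory bimodality, movement
    correlation and tube-resonance modelling, and a source-filter
    synthetic coda generator that supplies ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
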