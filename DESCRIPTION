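Package: psgpharm
Title: Sleep Polysomnography, Locus Ceruleus Spike-Train and
    Pharmacokinetic Analysis for Rodent Sleep Pharmacology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Epoch-based vigilance-state scoring of rodent EEG/EMG
    recordings, per-epoch Welch power spectra with relative band-power
    normalization, sleep-architecture statistics including the sleep
    fragmentation index, interspike-interval burst detection and
    dose-response normalization for locus ceruleus norepinephrine
    neurons, noncompartmental pharmacokinetics (Cmax, terminal
    half-life, AUC), relative quantification of qPCR Ct tables by the
    2^-ddCt method, and the accompanying statistical battery
    (D'Agostino-Pearson normality, one-way and mixed two-way
    repeated-measures ANOVA with Bonferroni post hoc tests). Ships a
    synthetic-data generator (semi-Markov hypnograms under a 12 h
    light/dark cycle, state-dependent EEG/EMG signals, Poisson spike
    trains with injected bursts, one-compartment absorption
    pharmacokinetic curves, two-reference-gene Ct tables) so every
    stage has a ground-truth parameter-recovery surface, plus EDF and
    CSV readers/writers for all artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
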