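Package: somnostress
Title: Rodent Sleep Staging, Slow-Wave Metrics and Social-Defeat Resilience Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing rodent polysomnography in social-defeat stress
    studies. Implements rule-based wake/NREM/REM/artifact staging of EEG/EMG
    recordings in 10 s epochs, FFT band-power spectra at 0.1 Hz resolution with
    normalized and relative slow-wave activity and cumulative slow-wave energy,
    sleep-bout architecture and sleep-restriction accounting, social-interaction
    ratio scoring with resilient/susceptible classification, and the accompanying
    statistics (mixed repeated-measures ANOVA with Holm-Sidak step-down post-hocs,
    Mann-Whitney U, power-based sample-size calculation). A synthetic
    polysomnography generator (semi-Markov hypnograms driven by a two-process
    homeostat, band-limited EEG/EMG synthesis, biased-random-walk arena
    trajectories) provides fully reproducible cohorts emulating a 12:12
    light:dark mouse study with sleep restriction and ten days of social defeat.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    car
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
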