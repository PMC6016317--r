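Package: kindleeg
Title: Quantitative EEG Analysis of Amygdala Kindling and Low-Frequency Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for afterdischarge (AD) EEG in the
    amygdala rapid-kindling model of temporal lobe epilepsy. Provides a seeded
    synthetic kindling-EEG generator with stage-dependent spectral calibration,
    an amplitude/duration AD detector (2.5x-baseline, >= 6 s rule), Hann-window
    50%-overlap Welch band-power decomposition into delta/theta/alpha/beta/gamma
    sub-bands and LFB/MFB/HFB aggregates with the theta/alpha ratio, and the
    group-level statistical layer (Lilliefors normality, one- and two-way ANOVA
    with Bonferroni post hoc, Kruskal-Wallis H, Pearson correlation between AD
    duration and band powers), orchestrated end to end by a deterministic study
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    car,
    nortest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
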