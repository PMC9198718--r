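Package: clc4quant
Title: Quantitative Analysis of ClC-4 Transporter Variants from Whole-Cell
    Recordings, Confocal Images and Gel Densitometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for disease-associated ClC-4
    Cl-/H+ exchanger variants. Generates synthetic whole-cell patch-clamp sweep
    sets (voltage-step protocol with P/8 leak subpulses), two-channel punctate
    fluorescence images and gel lane intensity profiles with known ground
    truth; processes raw sweeps into leak-subtracted traces, steady-state
    currents and integrated off-gating charges (Q_off); fits Boltzmann
    activation curves (V0.5), computes Q_off/current ratios, transport
    activities and expression-normalized current slope factors; quantifies
    Manders colocalization coefficients and gel-band fraction statistics; and
    applies the study's group-comparison scheme (Shapiro-Wilk and Levene
    gates, one-way ANOVA with Tukey HSD or Mann-Whitney tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    car,
    zoo,
    tiff,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
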