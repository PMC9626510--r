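Package: p300sep
Title: Single-Trial P300 Speller Decoding with a Separable Convolutional Network
Version: 0.1.0
Authors@R:
    person("BCI", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Simulation, preprocessing, and single-trial decoding of oddball
    P300 speller sessions recorded under augmented-reality (AR) or
    computer-screen (CS) stimulus presentation. Provides a seeded synthetic
    session generator (event schedule, ERP templates on pink/alpha/white noise
    background), the canonical preprocessing chain (channel dropping,
    zero-phase 0.1-12 Hz bandpass, 600 ms epoching, decimation to 200 samples),
    a depthwise-separable 1D convolutional network classifier with a standard
    CNN comparator, four classical baselines (shrinkage LDA, Bayesian LDA,
    stepwise LDA, linear SVM), and a nine-target evaluation harness (per-run
    accuracy, AUC, Wolpaw information transfer rate, paired t-tests, one-way
    ANOVA, cross-validation), with HDF5 session containers and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    rhdf5,
    stats,
    utils,
    yaml
Suggests:
    quadprog,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
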