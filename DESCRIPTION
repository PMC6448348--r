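Package: oscillosource
Title: Source-Level Unmixing of Oscillatory EEG Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of multichannel EEG with planted
    oscillatory cortical sources. Provides a three-concentric-spheres
    synthetic leadfield generator, empirical mode decomposition (EMD) and
    its noise-assisted multivariate variant (NA-MEMD) with a compiled
    sifting core, a smoothness-prior Bayesian inverse solver for source
    localization, reference electrode standardization (REST), Hilbert
    instantaneous attributes, circular-linear correlation between
    oscillation phase and a per-trial behavioral response, and
    cluster-based permutation tests over time and sensor-time. An
    orchestration layer compares sensor-level against source-level
    decompositions on simulated trials and links prestimulus phase to
    motor-evoked potential amplitude.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
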