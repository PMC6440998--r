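Package: switchfret
Title: Photon-Level Single-Molecule FRET Analysis of a Conformational Switch
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing diffusion-based single-molecule FRET
    measurements of fast conformational switching, built around the AAA+
    disaggregase ClpB M-domain system. Provides photon-level simulation of
    bursts under pulsed interleaved excitation, sliding-window burst detection
    with leakage and direct-excitation corrections, photon-by-photon hidden
    Markov inference of continuous-time multi-state kinetics with recoloring,
    dwell-time, segmentation and cross-correlation validation, thermokinetic
    post-processing (stationary populations, active/inactive ratios, Arrhenius
    free-energy profiles, binomial labeling statistics, Hill and binding
    isotherm fits), and FRET-restrained rigid-body triangulation of a mobile
    domain with accessible-volume dye modelling and steric-clash filtering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
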