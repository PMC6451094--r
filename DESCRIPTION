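Package: spfret
Title: Single-Pair FRET TIRF Trace Analysis and Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-pair FRET (spFRET) experiments on a
    dual-view TIRF microscope: synthetic two-channel movie and intensity-trace
    simulation with Markovian FRET-state switching, single-step photobleaching,
    spectral crosstalk and camera noise; bead-based channel registration, spot
    detection and aperture photometry; per-molecule crosstalk/gamma correction
    from acceptor-bleach steps and corrected FRET-efficiency traces;
    molecule-wise and frame-wise FRET histograms with constrained Gaussian
    mixture fits (including global amplitude-only fits); per-molecule
    Gaussian-emission hidden Markov models with Viterbi decoding, transition
    density plots, subpopulation assignment and dwell-time kinetics; and
    photobleaching-corrected mono-exponential survival analysis of molecule
    disappearance times for dissociation-rate estimation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    graphics,
    ggplot2,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
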