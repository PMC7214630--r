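Package: mecfes
Title: Myoelectrically Controlled Functional Electrical Stimulation:
    Estimation, Closed-Loop Simulation and Usability Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for myoelectrically controlled functional electrical
    stimulation (MeCFES), in which the intensity of electrical stimulation of
    paralysed finger flexors is driven continuously by the voluntary wrist
    extensor electromyogram. Implements the voluntary-muscle-contraction (VMC)
    estimation chain used during concurrent stimulation (second-order 16-500 Hz
    bandpass, per-pulse blanking windows, first-order inter-pulse comb filter,
    average rectified value, first-order IIR smoothing), the piecewise-linear
    stimulation controller with its three-button device state machine, a
    synthetic-signal generator for stimulated surface EMG (band-limited
    stochastic EMG, stimulation artifacts and M-waves, H-reflex/F-wave events,
    mains hum, motion artifacts, 16-bit quantization), a closed-loop simulator
    with latch-up (full-on) stability analysis, and scoring plus cohort
    statistics for the IPPA and QUEST assistive-technology outcome instruments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
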