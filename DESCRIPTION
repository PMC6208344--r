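Package: demyelin
Title: Compartmental Simulation of Demyelinated Cortical Neurons and
    Interhemispheric EEG Coherence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the electrophysiological consequences of
    demyelination and remyelination in deep-layer cortical pyramidal neurons
    and in resting-state mouse EEG. Includes a one-dimensional compartmental
    Hodgkin-Huxley cable model with a parameterizable axon initial segment
    (AIS), per-internode myelin wrap counts and lesion masks; an implicit
    (backward Euler) tridiagonal cable integrator with somatic current-clamp
    protocols, event classification (action potentials, back-propagating
    action potentials, spikelets) and threshold-current search; experiment
    drivers for AIS-length and myelin-wrap sweeps and proximal/distal lesion
    scenarios; a two-channel interhemispheric EEG pipeline (zero-phase FIR
    pre-filtering, 6 Hz cardiac-artifact removal, 2 s epoching, two-stage
    artifact rejection, a 30-filter log-spaced Hilbert filter bank, band
    relative power and time-domain real coherence); seeded synthetic-data
    generators for coherence-controlled EEG cohorts and weekly motor-score
    series; and the study statistics (exact 2x2 contingency test, two-stage
    adaptive FDR control, transient-deficit event detection, excess
    kurtosis).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
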