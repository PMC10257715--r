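Package: smfretr
Title: Single-Molecule FRET Trajectory Analysis for Conformational Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for two-colour single-molecule FRET (smFRET)
    TIRF experiments on surface-immobilized protein complexes, built around
    the closed/open conformational exchange of SEDS-bPBP peptidoglycan
    synthases such as RodA-PBP2. Covers spot detection and two-channel
    registration, donor/acceptor trace extraction with bleedthrough, direct
    excitation and gamma corrections, photobleach truncation and
    single-fluorophore quality control, ensemble hidden Markov model state
    segmentation with Viterbi paths, Gaussian-mixture fits of FRET-efficiency
    histograms, censored dwell-time kinetics with exponential fits and
    confidence intervals, transition-density maps normalized to observation
    time, and Forster distance-to-efficiency mapping. A ground-truthed
    simulator (Gillespie state paths, photophysics, camera model) makes every
    stage testable without raw movies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
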