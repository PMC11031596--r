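Package: tepstab
Title: Stability Analysis of TMS-Evoked Potentials
Version: 0.1.0
Authors@R:
    person("Pediatric", "Neurophysiology Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the within-block stability of transcranial
    magnetic stimulation evoked potentials (TEPs) recorded with EEG. Provides a
    seeded synthetic TMS-EEG generator emulating pediatric 64-channel recordings,
    an epoch preprocessing chain (autoregressive pulse-artifact interpolation,
    resampling, baseline correction, zero-phase filtering, robust bad-channel
    detection, amplitude-based trial rejection, common-average re-referencing),
    local TEP and global mean field amplitude summary waveforms, concordance
    correlation stability curves with a persistence-checked minimum number of
    pulses (MNP), marginal regression of MNP on experimental and clinical
    covariates via generalized estimating equations with an exchangeable working
    correlation, and a command-line driver for end-to-end simulated studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
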