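Package: gammakit
Title: Gamma Oscillation, Spike-Phase Coupling and Synaptic Current Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for in vitro hippocampal network
    electrophysiology: Welch band power of local field potential (LFP)
    gamma oscillations, autocorrelogram-based coefficient of rhythmicity,
    Hilbert-transform spike-phase coupling with circular statistics
    (Rayleigh test, preferred phase, Gaussian half-width), postsynaptic
    current event detection with charge-transfer quantification, exact
    one-tailed Wilcoxon and Mann-Whitney comparisons, and a synthetic-data
    generator for phase-locked spike trains and gamma-band LFP used to
    validate every estimator end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
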