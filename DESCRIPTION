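Package: syrinxspace
Title: Pressure Control-Space Analysis of Syringeal Sound Production
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for sound production of the isolated songbird
    syrinx driven by respiratory pressures. Reads calibrated multichannel
    recordings (sound, bronchial pressure, air-sac pressure, volumetric flow),
    conditions them with zero-phase Butterworth filters, computes sliding-bin
    acoustic and aerodynamic features (RMS, YIN fundamental frequency with
    aperiodicity and power gating, source level, Wiener entropy, mechanical
    efficiency), detects phonation threshold pressures on bronchial-pressure
    ramps, maps features over the bronchial by air-sac pressure control space,
    and fits piecewise frequency-pressure regressions with Bayesian information
    criterion model selection of the driving pressure. Includes a forward
    hemi-syrinx simulator with known ground truth for end-to-end recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
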