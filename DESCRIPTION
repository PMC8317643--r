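Package: restforge
Title: Restitution-Driven Calibration of Minimal Ventricular Action Potential Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes ventricular electrophysiologic remodeling from
    decremental-pacing data. Extracts activation-recovery intervals from
    unipolar electrograms by the Wyatt method, builds action potential
    duration restitution (APDR) curves with robust logarithmic fits,
    calibrates the four-variable minimal ventricular (Bueno-Orovio-
    Fenton-Cherry) cell model to cohort APDR targets with a genetic
    algorithm, quantifies calibration uncertainty by agglomerative
    hierarchical clustering of the fitted population, and assesses
    pro-arrhythmic behavior through single-cell alternans scans and 2-D
    monodomain re-entry inducibility sweeps. Includes a synthetic
    electrogram generator with per-beat ground truth so the whole
    pipeline is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    graphics,
    MASS,
    ape,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
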