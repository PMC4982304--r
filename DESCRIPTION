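Package: ppvtrack
Title: Pulse Pressure Variation Tracking from Arterial Blood Pressure
    Waveforms by Dual Marginalized Particle Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tracks an amplitude-modulated multi-harmonic model of the
    arterial blood pressure (ABP) waveform during spontaneous breathing
    with a dual maximum a-posteriori marginalized particle filter: two
    one-dimensional particle spaces follow the instantaneous respiratory
    and cardiac frequencies while an extended Kalman filter per particle
    marginalizes the sinusoidal and modulation coefficients.  From the
    tracked state the package computes continuous ABP envelopes, pulse
    pressure (PP) envelopes and the pulse pressure variation (PPV) index,
    together with a ground-truth synthetic-signal generator, a per-cycle
    manual-standard comparator, windowed PPV measurements and
    Bland-Altman agreement statistics.  Signals are read from plain CSV
    or PhysioNet WFDB (format 16) records, with anti-aliased decimation
    and mean-centering preprocessing.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
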