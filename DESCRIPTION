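Package: cardiomag
Title: Simulation and Deep-Learning Detection of Weak Cardiomyocyte Biomagnetic Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and detection tools for weak magnetic signals
    generated by cultured cardiomyocyte sheets. Provides ionic action-potential
    models for ventricular-type and pacemaker-like stem-cell-derived
    cardiomyocytes with genetic-algorithm conductance fitting, a 2D monodomain
    tissue solver (Crank-Nicolson), a Biot-Savart forward model for
    three-axis first-order gradiometric pickup coils, a synthetic background
    noise generator emulating a SQUID measurement environment, construction of
    labeled training corpora by superimposing simulated signals on noise, a
    Fourier synchrosqueezed transform + LSTM per-sample peak classifier with
    peak-region post-processing, and a scaled-template baseline detector.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
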