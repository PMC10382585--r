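Package: mpnstate
Title: Parametric Markov Multistate Models for Disease Progression in
    Myeloproliferative Neoplasms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multistate survival analysis of essential
    thrombocythemia (ET) and prefibrotic primary myelofibrosis (pre-PMF):
    a five-state progressive Markov model (diagnosis, thrombosis, overt
    myelofibrosis, blast phase, death) with ten transitions.  Provides
    counting-process data preparation from wide disease histories,
    maximum-likelihood estimation of parametric transition intensities
    (exponential, Weibull, Gompertz baselines with proportional-hazards
    covariates), transition-probability and state-occupation curves via the
    Kolmogorov forward equations, the nonparametric Aalen-Johansen
    estimator, per-transition Cox regression with delayed entry,
    IPSET-thrombosis and IPSET-survival risk scoring, and a calibrated
    synthetic-cohort generator for ET-like and pre-PMF-like populations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    graphics,
    grDevices,
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    Matrix,
    flexsurv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
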