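Package: tgimix
Title: Tumor Growth Inhibition Models with Delays and Nonlinear Mixed
    Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Structural models of chemotherapy-perturbed tumor growth in
    preclinical studies: the transit-compartment tumor growth inhibition
    system, an explicit delay-differential variant in which cell kill is
    delayed relative to drug exposure, and the classic generalized
    logistic, Gompertz and von Bertalanffy growth laws with their analytic
    solutions.  Population parameters are estimated by a stochastic
    approximation EM (SAEM) nonlinear mixed-effects algorithm with
    log-normal inter-individual variability and combined
    additive/proportional residual error; the marginal likelihood is
    estimated by importance sampling and candidate models are compared
    with AIC, AICc, BIC and information-criterion (Akaike) weights.  A
    synthetic cohort generator emulates longitudinal caliper measurements
    of mouse mammary tumors with weekend sampling gaps and
    euthanasia-threshold censoring, so the full pipeline is reproducible
    without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
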