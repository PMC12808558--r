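Package: pamdyn
Title: Dynamic Occupancy Modelling for Passive Acoustic Monitoring Programs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to turn classifier prediction tables from large-scale
    passive acoustic monitoring (PAM) programs into weekly encounter
    histories, fit Bayesian dynamic (multi-season) occupancy models with
    fire-disturbance covariates and forest-level random intercepts, and
    derive occupancy trajectories, annual growth rates (lambda-bar),
    probability-of-direction summaries and MacKenzie-Bailey goodness-of-fit
    checks at multiple spatial scales. Includes a synthetic-data generator
    that emulates landscapes, fire histories, latent occupancy dynamics,
    nightly detections and classifier output so every stage of the pipeline
    is testable without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    rjags,
    coda,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
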