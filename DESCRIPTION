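Package: adaptsms
Title: Simulation and Analysis of a Bayesian Adaptive Factorial SMS
    Vaccination-Reminder Trial
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to simulate and analyse a Bayesian response-adaptive
    factorial randomised trial of SMS vaccination reminders. Provides a
    synthetic generator for clinics, families and scheduled vaccine
    occasions; mass-weighted urn randomisation with response-adaptive
    reallocation; SMS scheduling, eligibility and on-time-vaccination
    endpoint logic; five pre-specified Bayesian factorial logistic models
    (full interaction, no interaction, framing only, timing only, and a
    shared pooled reminder effect) with Laplace and MCMC engines; interim
    analysis triggers, control-arm discontinuation rules and allocation
    retargeting; and replicate-trial estimation of operating
    characteristics (power and type I assertion probability) with
    null-calibration of the superiority threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    rjags,
    coda,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
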