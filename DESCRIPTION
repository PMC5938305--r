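Package: gamblehurdle
Title: Two-Part Gamma Hurdle Mixed Models for Gambling Trial Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-arm randomized trials of problem-gambling
    treatment with timeline-followback (TLFB-G) outcomes. Implements a Bayesian
    two-part (Bernoulli x gamma) mixed model for zero-heavy weekly gambling-loss
    data with restricted-cubic-spline time, a discontinuous treatment-start jump
    and a shared-baseline constraint; Bayesian linear mixed models for
    questionnaire outcomes (NODS, PHQ-9, GAD-7) with categorical time; scoring
    and severity bands for the NODS, PGSI, PHQ-9, GAD-7 and AUDIT instruments
    plus trial eligibility rules; posterior predictive checks; a Monte Carlo
    frequentist-coverage harness; and a synthetic-trial generator with
    binge-structured losses and missing-at-random dropout.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
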