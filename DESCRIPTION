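Package: tempodisc
Title: Temporal Discounting, Choice Consistency, and Relapse Survival Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and estimation pipeline for binary intertemporal
    choice experiments. Implements the hyperbolic value function with a
    softmax decision rule, an adaptive staircase calibration that titrates
    per-delay indifference points and fits a pre-scan discount rate k by
    ordinary least squares, construction of individualized 90-trial offer
    sets under fixed design constraints (mean subjective value 30 EUR,
    twentyfold value range, half/half split around the immediate amount),
    and sequential Bayesian estimation of the discount rate k and inverse
    temperature beta on a discretized log-scale grid, yielding the
    posterior variance var(k) as a trial-by-trial index of choice
    consistency. A synthetic-cohort generator plants group-level parameter
    distributions, nicotine-dependence covariates, and proportional-hazards
    relapse times so that the downstream statistical stage (group
    contrasts, longitudinal tests, Cox survival models of relapse) can be
    exercised and validated end to end without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
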