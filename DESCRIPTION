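Package: survlc
Title: Survival Learning Curves with Shared Gamma Frailty and Restricted
    Mean Survival Time
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling surgical learning curves from clustered
    time-to-event data with provider heterogeneity.  Implements shared
    gamma-frailty Cox models fit by an EM algorithm with a profile
    likelihood for the frailty variance, restricted mean survival time
    (RMST) from Kaplan-Meier curves and from frailty-model baselines, a
    four-shape parametric learning-curve framework (exponential, power
    series, logarithmic, log-normal) with multilevel physician- and
    center-level predictions and a survival-time update rule, a random
    survival forest backend, a seeded synthetic cohort generator for
    external-ventricular-drain-like multicenter data, and a factorial
    simulation engine over operator counts, censoring rates, and
    learning-curve shapes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    ranger,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
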