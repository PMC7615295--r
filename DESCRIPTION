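Package: nisurv
Title: Population-Level Summary Measures for Non-Inferiority Survival Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation and testing of three population-level summary
    measures for two-arm randomised trials with time-to-event outcomes:
    the hazard ratio, the difference in restricted mean survival time and
    the difference in survival at a fixed time point. All three measures
    can be obtained from a single flexible parametric proportional-hazards
    survival model (a restricted cubic spline for the log cumulative
    baseline hazard on log time) with delta-method confidence intervals,
    or non-parametrically via Kaplan-Meier estimation with the Greenwood
    variance. Includes matching of non-inferiority margins across the
    three scales under an exponential control-arm reference, a trial
    simulator with uniform accrual and administrative censoring, and a
    Monte-Carlo harness for estimating power and type-I error of the
    resulting one-sided tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    pracma,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    flexsurv,
    jsonlite
Config/testthat/edition: 3
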