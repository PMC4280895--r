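Package: survassure
Title: Assurance and Power Calculations for Two-Arm Survival Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assurance (the unconditional, prior-averaged probability of a
    successful trial) and power calculations for two-arm randomised clinical
    trials with time-to-event endpoints. Supports exponential and Weibull
    survival models and a nonparametric proportional-hazards model analysed
    with the logrank test, all with uniform patient accrual over a limited
    recruitment period and administrative censoring at the end of follow-up.
    Includes prior elicitation from quartile or trial-roulette judgements
    about survival rates, power priors for historical control data, and a
    Dirichlet-process posterior for the control survivor function fitted to
    right-censored historical data by Gibbs sampling.
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
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
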