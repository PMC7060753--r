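Package: tsdnorm
Title: Thermal Reaction Norms for Temperature-Dependent Sex Determination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of the thermal reaction norm linking constant
    incubation temperature to hatchling sex ratio in species with
    temperature-dependent sex determination. Fits the symmetric logistic
    and the asymmetric flexit sigmoid models to male/female counts by
    binomial maximum likelihood, derives pivotal temperatures and
    transitional ranges of temperatures (TRT) with confidence intervals
    from Hessian-based resampling, measures goodness of fit by deviance
    against both the chi-squared approximation and a simulated null
    distribution, compares models and datasets with AICc, Akaike weights,
    BIC and BIC weights (w-values), and provides an adaptive
    Metropolis-Hastings sampler for Bayesian credibility intervals.
    Includes the complete published constant-temperature incubation
    dataset for olive ridley sea turtles (Lepidochelys olivacea) and a
    binomial simulator for power and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
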