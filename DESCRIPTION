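Package: gmcenter
Title: Grand-Mean Comparisons of Centers for Central Statistical Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares every center of a multicenter clinical trial or patient
    registry with the sample-size-weighted average (the Grand Mean) of all
    centers, for continuous, binary and ordinal outcomes. Deviations of center
    parameters from the Grand Mean are tested simultaneously with single-step
    multiplicity adjustment based on the multivariate t or normal distribution,
    and reported with adjusted p-values, simultaneous confidence intervals and
    optional equivalence-margin classification. Estimation backends include the
    one-way linear model, the binomial logit GLM, Firth-type bias-reduced
    logistic regression, Bayesian logistic regression with Cauchy priors, and
    nonparametric relative effects (pseudo-ranks) for continuous and ordinal
    data. A Monte Carlo engine reproduces familywise type I error and power
    studies over balanced and unbalanced center-size grids.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    readr,
    mvtnorm,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
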