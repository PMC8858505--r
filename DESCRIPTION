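Package: subborrow
Title: Bayesian Borrowing of Treatment-Effect Information Between Trial Subgroups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates a treatment effect (risk difference) in a small target
    subgroup of a randomised trial while borrowing a controlled amount of
    information from a larger subgroup in the same trial, via a conjugate
    normal commensurate prior whose commensurability parameter is the prior
    standard deviation of the treatment-by-subgroup interaction. Provides the
    closed-form posterior, conversions between the interaction prior and the
    relative weight allocated to the borrowed data, effective sample size,
    tools for eliciting and pooling expert opinion on the interaction
    (range-and-coverage to normal mapping, median pooling, consensus checks,
    weight/uncertainty feedback tables), and Monte-Carlo evaluation of the
    design (predictive power of the borrowing analysis and standalone
    frequentist power), with tidy tibble outputs, broom-style tidy()/glance()
    methods and ggplot2 forest plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    yaml
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
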