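Package: bfdesign
Title: Bayes Factors for Superiority, Equivalence, and Non-Inferiority
    Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bayes factor hypothesis tests for two-group designs with
    continuous outcomes, covering the three designs most common in
    clinical and biomedical research: superiority, equivalence, and
    non-inferiority. The standardized effect size carries a Cauchy prior
    (default scale 1/sqrt(2)); the nuisance variance carries a Jeffreys
    prior and is integrated out analytically through the noncentral-t
    sampling distribution of the two-sample t statistic. Point,
    one-sided, and interval hypotheses are supported, data may be
    supplied as raw outcome vectors, as per-group summary statistics, or
    as group means plus a confidence interval for the mean difference,
    and Savage-Dickey density curves and companion frequentist tests
    (one-sided t, TOST) are provided. All Bayes factor arithmetic is
    carried out in log space. A brute-force (delta, sigma^2) integration
    oracle is included for independent certification of the engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
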