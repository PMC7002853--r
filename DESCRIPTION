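Package: smde
Title: Standardized Mean-Difference Effect Sizes Under Unequal Variances
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Point estimates, sampling variances and exact noncentral-t
    confidence intervals for standardized mean-difference effect sizes:
    the classical pooled-variance estimators (Cohen's g, Hedges' d,
    Glass' Delta, Bonett's delta-hat), a Welch-based effect size for two
    groups with unequal population variances, and an unbiased effect
    size for the difference between a mean and a known constant.  Exact
    small-sample bias correction uses the gamma-function coefficient
    J(m) evaluated in log space at fractional Welch-Satterthwaite
    degrees of freedom.  Includes a Monte Carlo harness for studying
    estimator bias and confidence-interval width over grids of sample
    sizes and variance ratios, file-based input of grouped data, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
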