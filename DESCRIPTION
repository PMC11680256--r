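Package: healthineq
Title: Summary Measures of Health Inequality from Disaggregated Data
Version: 0.1.0
Authors@R: person("healthineq", "maintainers", role = c("aut", "cre"),
    email = "maintainers@example.org")
Description: Computes sixteen summary measures of health inequality
    (difference, ratio, concentration indices, slope and relative indices
    of inequality, mean-difference and variance-family measures, the Theil
    index, and population attributable risk and fraction) with confidence
    intervals from disaggregated indicator data, one row per population
    subgroup. Supports binary, ordered, and non-ordered dimensions of
    inequality, eligibility filtering, cross-setting comparison (medians,
    interquartile ranges, Spearman correlation matrices), a synthetic-data
    generator with binomial survey noise for validation, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
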