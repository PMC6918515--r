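Package: hwdisparity
Title: State-Level Healthy Weight Disparity Indices Under National and
    State-Specific Reference Frames
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds income-by-BMI health disparity indices for U.S. states
    from BRFSS-style survey microdata and compares the state rankings they
    induce. Implements the Healthy Weight Disparity Index (HWDI), which
    measures income-group deviations in adjusted mean BMI from the fixed
    24.9 kg/m^2 healthy-weight ceiling, and a revised index (RHWDI) that
    replaces the national reference with each state's own adjusted mean BMI
    and replaces fixed dollar income cut points with a poverty-guideline
    ratio classification (185% of the federal poverty level; state-specific
    75th percentile). Includes a synthetic BRFSS-like microdata generator
    with configurable income-BMI gradients and missingness, a chained-
    equations multiple-imputation engine (linear, predictive mean matching,
    and logistic steps), survey-weighted covariate-adjusted group means via
    marginal standardization, magnitude-based state rankings, and rank
    concordance statistics (Spearman's rho with Bonferroni adjustment,
    tercile Cohen's kappa, rank-difference summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
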