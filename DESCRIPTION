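Package: trialmargins
Title: Standardized Differences and Sample-Size Margins in Two-Arm Trials
Version: 0.1.0
Authors@R:
    person("Registry", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the differences that two-arm randomized
    clinical trials are designed to detect (superiority) or rule out
    (noninferiority). Implements standardized differences in proportions and
    in means, forward sample-size formulas for the four design-by-outcome
    combinations with a Monte-Carlo power oracle, inverse power analysis that
    reconstructs missing planning parameters from the reported sample size,
    a calibrated synthetic trial-registry generator, and the comparison
    analysis stage (group contrasts, interaction tests, and main-effects
    ANOVA with balanced adjusted means) together with an end-to-end pipeline
    and command-line driver.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
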