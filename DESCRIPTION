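Package: flexpst
Title: Flexible P-Value Significance Thresholds for Two-Arm Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the flexible p-value significance threshold (PST) that
    minimizes a weighted sum of type I and type II error for a two-arm trial
    analyzed with Welch's unequal-variance t test. Provides Welch's test from
    per-arm summary statistics with Welch-Satterthwaite degrees of freedom,
    the weighted error cost function and its stationarity equation, a robust
    bracketed solver for the optimal critical value, a likelihood-ratio /
    posterior-odds Bayesian alternative, and a seedable Monte Carlo simulator
    that compares fixed thresholds (0.05, 0.005) against flexible thresholds
    on false-positive rate, false-negative rate, and weighted error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
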