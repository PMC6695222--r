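Package: riskpool
Title: Simulation and Analysis of a Need-Based Transfer Risk Pooling Game
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a two-player economic game of resource management under
    environmental volatility, in which paired players can pool risk by
    transferring resources to one another. Resources follow a strong-Allee
    growth rule with configurable volatility regimes and mean-zero random
    shocks; players harvest for earnings and drop out after three consecutive
    periods below a survival threshold. The package provides need-based
    (osotua-style), debt-based (esile-style), no-transfer, and stochastic
    human-like decision policies; computes seven behavioral variables per
    player (repetitive giving, repetitive asking, mean amounts requested and
    given, requests made, requests answered positively, and matching between
    amounts given and received); and compares experimental groups with
    independent-samples t tests, Cohen's d, Bonferroni-adjusted alpha levels,
    and a one-way ANOVA pooling check with Scheffe post-hoc contrasts. A
    synthetic-experiment generator with effect-size calibration stands in for
    human sessions so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
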