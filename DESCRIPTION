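Package: medmultiverse
Title: Multiverse Analysis of Single-Mediator Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess the robustness of mediation analysis results
    against data-analytical decisions. Declares decision points (determinant
    coding, confounder sets and selection strategy, age moderation,
    determinant-mediator interaction), enumerates every combination into a
    multiverse of analysis specifications, estimates traditional
    (product-of-coefficients) and causal (pure/total natural direct and
    indirect) mediation effects with Monte Carlo confidence intervals in each
    universe, and summarises robustness with two-panel specification curves.
    Includes a seeded synthetic-data generator emulating a cohort-study
    weight-change / fat-mass / bone-mineral-density mediation example, plus
    Edwards-Nunnally change categorisation, change-in-estimate confounder
    selection, and simple-slopes moderation.
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
    MASS,
    patchwork,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
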