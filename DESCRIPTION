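Package: ccitrend
Title: Composite Coverage Index Trends, Projections and Equity in LMICs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reproductive, maternal, newborn and child health (RMNCH)
    coverage monitoring in low- and middle-income countries. Computes the
    Countdown composite coverage index (CCI) from its eight indicator
    proportions, fits Bayesian hierarchical linear models to logit-transformed
    CCI panels (country within region random intercepts, residence, wealth
    quintile or maternal education strata, time-varying covariates), projects
    coverage to 2030 with credible intervals and probabilities of reaching the
    80 percent universal health coverage target, aggregates countries to
    regions by random-effects meta-analysis over posterior draws, and
    quantifies within-country inequality via the urban-rural gap and the slope
    index of inequality. Includes a synthetic survey-panel generator with known
    ground truth, model checking (variance inflation factor screening, DIC,
    posterior predictive checks, Gelman-Rubin diagnostics, prior sensitivity)
    and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    withr,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
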