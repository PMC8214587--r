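Package: markovcea
Title: Markov Cohort Cost-Effectiveness Modelling for First-Line NSCLC
    Immunotherapy Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for cost-effectiveness analysis of
    first-line treatment strategies in metastatic non-squamous non-small cell
    lung cancer with high PD-L1 expression (pembrolizumab monotherapy,
    pembrolizumab plus chemotherapy, and chemotherapy). Fits parametric
    survival distributions to individual-level or digitized Kaplan-Meier data
    with AIC/BIC model selection, reconstructs pseudo individual patient data
    from digitized curves, runs a 3-state Markov cohort model (progression-free,
    progressive disease with second-line tunnel states, death) on monthly
    cycles with half-cycle correction, accrues discounted costs and QALYs,
    computes incremental cost-effectiveness ratios and the efficiency frontier,
    and quantifies uncertainty through one-way (tornado) and probabilistic
    sensitivity analyses with cost-effectiveness acceptability curves, plus a
    set of structural scenario analyses. A synthetic-data module generates
    survival data, emulated digitized curves with risk tables, and complete
    cost/utility/strategy configurations so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    flexsurv,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
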