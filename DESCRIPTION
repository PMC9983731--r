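Package: nutrientlag
Title: Watershed Nutrient Balances, Legacy-Lag Regression, and River Load
    Trend Attribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for attributing long-term trends in flow-normalized river
    nutrient loads to watershed drivers. Computes annual nitrogen and
    phosphorus mass balances from input/output component series (fertilizer,
    manure, wastewater effluent, atmospheric deposition, biological fixation,
    rock weathering, crop harvest, and gaseous emissions), nonparametric
    Theil-Sen trends, watershed retention, and TN:TP stoichiometry. Fits
    distributed-lag regressions of river loads on current and lagged nutrient
    balances plus polynomial-in-year latent terms, using AR(1) pre-whitened
    lag-correlation screening and exhaustive best-subset selection by BIC, and
    quantifies driver impacts with counterfactual scenarios that freeze either
    the balance regressors or the latent year terms at baseline levels. A
    synthetic watershed generator with recorded ground truth supports
    end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
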