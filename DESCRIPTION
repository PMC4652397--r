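Package: radonvuln
Title: Threshold-Indexed Radon Vulnerability Classification and Ecologic
    Lung Cancer Mortality Trends
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An ecologic pipeline for evaluating indoor radon guideline
    values over small spatial mapping units. Units with indoor radon
    measurements are labelled high or low vulnerability according to
    whether their observed 95th percentile concentration meets each
    threshold in a ladder (50 to 600 Bq/m3); a class-balanced bootstrap
    forest classifier is trained per threshold and evaluated out-of-bag
    (per-class accuracy and precision, Cohen's kappa, kappa gain between
    adjacent thresholds, Geary's c spatial autocorrelation diagnostics);
    predictions are extended province-wide with an eligibility rule,
    populations at risk are estimated by areal apportionment, and crude
    lung cancer mortality ratios are stratified by vulnerability class,
    smoking prevalence and sex and smoothed with a tricube local
    regression. A synthetic-study generator with known ground truth
    emulates the data structure so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0),
    randomForest,
    optparse
Config/testthat/edition: 3
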