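Package: crcrisk
Title: Polygenic and Lifestyle Risk Stratification for Colorectal Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analytic modelling of colorectal cancer risk stratification from
    combined polygenic and lifestyle risk factors. Builds the log-normal
    relative-risk distribution of a polygenic risk score from a SNP panel,
    folds in nongenetic risk factors as multiplicative level/category effects,
    and derives discrimination (ROC AUC), percentile relative risks, and
    minimum/maximum risk-allele counts for percentile thresholds. Fits
    parametric distributions to interval-censored exposure survey data and
    discretizes continuous exposures into risk-factor levels. Computes
    age-conditional absolute risks from banded incidence and mortality rate
    tables under competing mortality, screening-eligibility stratification,
    and prevention-impact (risk difference) estimates for lifestyle and
    chemoprevention scenarios. Includes generators for synthetic SNP panels,
    censored exposure surveys, and vital-statistics rate tables so the full
    analysis is reproducible without restricted survey or registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    fitdistrplus
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
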