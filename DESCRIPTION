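Package: crcrisk
Title: Colorectal Cancer Risk Stratification with a Polygenic Risk Score and Family History
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a population-normalised multiplicative polygenic risk
    score from a SNP panel of per-allele odds ratios and risk-allele
    frequencies, combines it with centred family-history relative risks,
    converts the combined relative risk to absolute 10-year and lifetime
    colorectal cancer risks from age- and sex-specific incidence and
    mortality rate tables, and evaluates the resulting model with
    standardised incidence ratios (Poisson log-likelihood confidence
    intervals), risk-quantile stratification, ROC discrimination, and
    calibration-slope (dispersion) testing. Includes a cohort simulator
    (Hardy-Weinberg genotypes, Gompertz rate tables, hazard-driven
    outcomes with censoring) so the full pipeline is testable without
    restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pROC,
    vcfR,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
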