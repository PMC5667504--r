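Package: quadnb
Title: Differential RNA Methylation Analysis for MeRIP-Seq Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential RNA methylation (m6A) analysis for count-based
    MeRIP-Seq data at small sample size. Models the IP and input-control
    read counts of each feature under two experimental conditions with four
    cross-linked negative binomial distributions whose means and variances
    are tied together through shared abundance, methylation-rate and
    expression parameters, with the extra-Poisson ("raw") variance estimated
    by a gamma-family smooth over methylation rate and abundance. Provides
    an exact conditional two-sided test for differential methylation, risk
    and odds ratios, library size-factor estimation (median-of-ratios or
    totals), a ground-truth simulator of overdispersed IP/input count
    matrices, ROC/AUC benchmarking and a sample-swop (label exchange)
    empirical-FDR protocol, plus a small command-line interface.
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
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    DESeq2,
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
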