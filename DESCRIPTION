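Package: crpfrailty
Title: Frailty-Index Cohort Analysis and Summary-Statistic Genetics for
    Inflammation and Frailty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the relationship between a circulating
    inflammation biomarker (high-sensitivity C-reactive protein, hs-CRP)
    and frailty measured by a deficit-accumulation frailty index.
    Implements the frailty index with chained-equation imputation and
    tertile-based logistic models (including restricted-cubic-spline
    non-linearity and subgroup/interaction analysis); LD-score regression
    for SNP heritability and cross-trait genetic correlation with
    block-jackknife uncertainty; a composite-null pleiotropy scan based on
    the product of z-scores with its normal-product tail distribution,
    LD clumping and locus merging; and a full two-sample Mendelian
    randomization suite (IVW, MR-Egger, weighted median, mode estimators,
    Cochran's Q, leave-one-out, MR-PRESSO, maximum likelihood, penalized
    IVW and robust adjusted profile score). A synthetic-data module
    generates two-wave deficit cohorts and paired GWAS summary statistics
    with known heritability, genetic correlation, sample overlap and
    causal effects so every stage is testable without individual-level
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
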