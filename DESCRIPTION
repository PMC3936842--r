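Package: agreemeta
Title: Generalizability of Mean Difference Versus Standardized Mean
    Difference in Meta-Analysis of Continuous Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the mean difference (MD) and the
    standardized mean difference (Hedges' adjusted g) as effect measures
    for meta-analyses of continuous outcomes. Implements per-trial effect
    sizes with sampling variances, inverse-variance fixed-effect and
    DerSimonian-Laird random-effects pooling with Cochran's Q, tau-squared
    and I-squared, a leave-one-out percentage-agreement statistic that
    quantifies how often a single trial's estimate falls inside the pooled
    confidence interval of the remaining trials, paired exact sign tests
    and McNemar tests contrasting the two metrics across a corpus of
    meta-analyses, and a calibrated generator of synthetic two-arm trial
    summary corpora for validating the whole pipeline.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
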