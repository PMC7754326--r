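Package: smallstudy
Title: Small-Study Effects in Multivariate Meta-Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tests for small-study effects (funnel-plot asymmetry) when a
    meta-analysis reports several, partially overlapping outcomes. Fits the
    flexible hybrid meta-regression of an effect estimate on its standard
    error with a heterogeneity-inflated, scale-free variance, via a two-step
    procedure: the between-study variance is estimated from the marginal
    random-effects model and a variance-stabilising transformation reduces
    the fit to ordinary least squares. Cross-outcome covariance of the
    regression estimates is obtained with a working-independence sandwich
    estimator restricted to the studies reporting both outcomes, yielding a
    global Wald chi-squared test that all small-study slopes are zero, with a
    Shaffer-type sequentially rejective multiple-testing step. Includes the
    classical Egger regression, the Lin-Chu maximum-likelihood model, a
    synthetic meta-dataset simulator and a type-I error / power harness.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr, metafor, yaml, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
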