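Package: pehscreen
Title: Renal Variant Screening for the Ambulatory Blood Pressure Response
    to Acute Exercise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of a candidate-gene analysis of
    postexercise hypotension: construction of the hourly ambulatory blood
    pressure response phenotype with manufacturer-range quality control,
    minor-allele genotype coding from a merged VCF, per-variant longitudinal
    screening with first-order autoregressive (AR1) within-subject errors fit
    by profiled maximum likelihood, Bonferroni and Benjamini-Yekutieli
    adjustment over the universe of unique genotype profiles, final
    multivariable models with Magee pseudo-R-squared and partial proportion of
    variance explained, and a parametric simulation of the screen's power.
    Includes a synthetic cohort generator emulating the full study design so
    every stage is testable without subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nlme,
    yaml,
    optparse,
    withr,
    Matrix,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
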