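---
title: "Methods: longitudinal screening of renal-pathway variants for postexercise hypotension"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal screening of renal-pathway variants for postexercise hypotension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scientific setting

Postexercise hypotension (PEH) is the sustained fall in blood pressure after
a single bout of aerobic exercise. A common study design measures each
participant's ambulatory blood pressure over the ~19 waking-and-sleep hours
following three randomized sessions — a non-exercise control, a moderate
bout, and a vigorous bout — and asks whether variants in renal
blood-pressure-regulating genes (renin–angiotensin–aldosterone system,
adducin) modify the response. `pehscreen` implements that analysis chain:
phenotype construction, genotype coding, a per-variant longitudinal screen,
multiplicity control, final multivariable models, and a power simulation.
A synthetic cohort generator emulates the design so every stage is testable
without subject-level data.

## Phenotype

Ambulatory readings are quality-controlled with fixed manufacturer-style
bounds (a reading is removed iff SBP > 220 or < 80 mmHg, or DBP > 130 or
< 40 mmHg), a subject-session requires at least 80% of expected readings,
and readings are averaged within half-open hour bins `[60(h-1), 60h)` after
the session. The hourly *response* is the change from the pre-session
baseline under exercise minus the same change under control, so stable
subject-level offsets cancel:

\[ y_{ih} = (\mathrm{BP}^{ex}_{ih} - \mathrm{BP}^{ex}_{i,base}) -
           (\mathrm{BP}^{ctl}_{ih} - \mathrm{BP}^{ctl}_{i,base}). \]

`compute_aasi()` provides the ambulatory arterial stiffness index,
`1 - slope(DBP ~ SBP)`, as a descriptive covariate.

## Screening model

For each variant, within one ethnicity × intensity × outcome family, the
hourly response is modelled as

\[ y_{ih} = \beta_0 + \beta_1 t + \beta_2 t^2 + \beta_3 t^3 +
            g_i(\beta_4 + \beta_5 t + \beta_6 t^2 + \beta_7 t^3) +
            \varepsilon_{ih}, \]

with `t = hour − 10` (centering tames collinearity of the cubic) and
`g_i ∈ {0,1,2}` the subject's minor-allele count. Errors are mean-zero
Gaussian, independent across subjects, with a within-subject correlation
structure: first-order autoregressive (AR1, `cor = ρ^{|Δt|}`, the
continuous-lag form so missing hours are handled exactly), compound
symmetry (CS), or independence. The variant's screening p-value is the
4-degree-of-freedom maximum-likelihood likelihood-ratio test of the four
genotype terms against the time-only model, referred to a χ²₄ distribution
(a residual-degrees-of-freedom F reference is available).

### Estimation

`fit_ar1()` is written from first principles rather than delegating to a
mixed-model package. For a candidate ρ the model is *whitened* in closed
form — AR1 by the innovations transform
`w_j = (x_j − ρ^{d_j} x_{j−1}) / sqrt(1 − ρ^{2 d_j})` with `d_j` the time
gap, CS by its closed-form eigen-structure — after which generalized least
squares reduces to ordinary least squares on the whitened data. The error
variance and the regression coefficients are profiled out analytically,
leaving a one-dimensional profiled log-likelihood in ρ that is maximized by
bounded search on (−0.99, 0.99) with tolerance 1e-8. Both ML and REML
objectives use the conventions of standard GLS software, and the test suite
cross-checks coefficients, standard errors, ρ, and log-likelihoods against
both a dense brute-force block-covariance oracle and `nlme::gls`.

```{r}
library(pehscreen)
des <- ar1_design(responses, ma, outcome = "sbp")
full <- fit_ar1(des$y, des$X_full, des$subject, des$time, method = "ML")
reduced <- fit_ar1(des$y, des$X_reduced, des$subject, des$time, method = "ML")
loglik_ratio_test(full, reduced)
```

## Genotypes and multiplicity

`ingest_vcf()` reads a merged VCF v4.2 with `vcfR`, keeps `FILTER == PASS`
records, splits multi-allelic sites into per-ALT biallelic records, and
codes each variant as the count of the *cohort minor* allele (ALT counts
are flipped when the pooled ALT frequency exceeds 0.5; a 0.5 tie keeps
ALT). Missing genotypes are `NA`.

Variants that share an identical genotype column within the analyzed
subgroup give identical tests, so the multiplicity universe is the number
K of *unique polymorphic genotype profiles* (`build_profile_universe()`).
Within each family, raw p-values are adjusted by Bonferroni (`min(1, pK)`)
and by Benjamini–Yekutieli (delegated to `stats::p.adjust(..., "BY", n =
K)`, whose `c(K) = Σ 1/j` inflation is valid under arbitrary dependence);
a variant advances if the Bonferroni value is below 0.05 or the BY value
below 0.20. SBP and DBP families are corrected separately within
ethnicity × intensity.

## Final models and variance explained

For variants that pass, `select_covariates()` admits subject-level
covariates (age, BMI, log-transformed insulin, triglycerides,
endothelin-1) by single-covariate ML likelihood-ratio tests,
`select_model()` picks the correlation structure by AIC, and
`fit_final()` reports REML coefficients plus ML-based Magee pseudo-R²

\[ R^2_M = 1 - \exp\{ \tfrac{2}{n} (\ell_R - \ell_U) \}, \]

with `n` the number of *subjects* and the reference model an
intercept-plus-correlation fit. The genotype's partial proportion of
variance explained is the difference of `R²_M` between the full model and
the model without genotype terms; for nested ML fits it is nonnegative by
construction. Because `n` counts subjects while the likelihood accumulates
over all hourly observations, `R²_M` saturates quickly as within-subject
replication grows — it is comparable across models on the same data, not
across designs.

## Power simulation

`estimate_power()` simulates responses from a fitted (β, σ², ρ) with the
cohort's genotypes fixed, and tests the genotype terms with an F statistic
whose denominator degrees of freedom are `n_obs − rank(X)`. The default
fast mode fixes ρ at its estimate and vectorizes simulation over a
precomputed whitened QR decomposition; `refit_rho = TRUE` re-estimates ρ
in every replicate (slower, used as a cross-check). Power is the rejection
fraction, reported with its binomial standard error.

## Synthetic cohort generator

`simulation_config()` / `simulate_cohort()` emulate the study design: two
ethnic groups (default 14 and 9 subjects), genotypes drawn
Binomial(2, MAF) per group, three sessions, three readings per waking hour
(hours 1–13) and two per sleep hour (14–19), a 10-reading pre-session
baseline, latent hourly response equal to a cubic time trend plus additive
per-allele genotype effects plus AR1 noise, independent reading noise,
and artifacts drawn uniformly from the excluded QC ranges. The control
session is flat at resting pressure, so the constructed response equals
the latent trend plus noise by design. `write_cohort()` emits the VCF,
covariate, reading, baseline, and amplicon-manifest files consumed by
`run_pipeline()`. The generator reproduces the design's *structure*
(timing, missingness, QC, correlation), not any real cohort's allele
frequencies or effect sizes; defaults are fixed design choices, not tuned
quantities.

Determinism: all stochastic stages take integer seeds below 2³¹ and derive
per-stage substreams with `substream_seed()`, so a pipeline run is
byte-reproducible.

## Numerical choices

- ρ is searched on (−0.99, 0.99); a boundary maximum is flagged.
- Aliased design columns are dropped by pivoted QR with a warning.
- Likelihood conventions match `nlme::gls` exactly (ML: σ̂² = RSS/N;
  REML: σ̂² = RSS/(N−p) with the `log|X*'X*|` term), enabling independent
  cross-checks.
- The χ² reference for the 4-df screen is asymptotic; at very small group
  sizes the residual-df F option is the conservative alternative, and
  `fit_final()` flags genotype groups of size 1 as potential overfits.

## Limitations

- Marginal GLS only: no subject-level random effects, no GEE, no genomic
  control.
- The screen assumes Gaussian hourly responses; heavy-tailed artifacts are
  handled only through the QC bounds.
- Magee R² values depend on the subject-count convention above and should
  not be read as fractions of total variance.
- The bundled worked-example fixture is a synthetic construction matching
  published group-level summary cells exactly; it contains no subject data.
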