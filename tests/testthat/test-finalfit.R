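# Final models: covariate eligibility, AIC selection, Magee pseudo-R2 and
# partial PVE.

test_that("Magee pseudo-R2 closed forms and monotonicity", {
  expect_equal(magee_r2(-100, -100, 10), 0)
  expect_equal(magee_r2(-95, -100, 10), 1 - exp(-1))
  lls <- seq(-100, -80, by = 5)
  r2 <- vapply(lls, magee_r2, numeric(1), llR = -100, n = 12)
  expect_true(all(diff(r2) > 0))
  expect_error(magee_r2(-101, -100, 10), "higher likelihood")
})

test_that("covariate eligibility: strong predictors in, constants out, noise ~5%", {
  set.seed(40)
  n <- 40
  d <- make_model_responses(n, sigma = 4)
  subj <- unique(d$subject)
  sm <- tapply(d$sbp, d$subject, mean)[subj]
  covars <- data.frame(subject = subj,
                       strong = sm + rnorm(n, 0, 0.3),
                       flat = 1,
                       noise = rnorm(n))
  sel <- select_covariates(d, covars, c("strong", "flat", "noise"))
  expect_true(sel$eligible[sel$covariate == "strong"])
  expect_false(sel$eligible[sel$covariate == "flat"])
  expect_equal(sel$reason[sel$covariate == "flat"], "constant")
  # pure-noise eligibility rate over repeated draws is near alpha
  hits <- 0L
  for (r in 1:60) {
    covars$noise <- rnorm(n)
    s <- select_covariates(d, covars, "noise")
    if (s$eligible) hits <- hits + 1L
  }
  expect_lte(hits, 9L)     # binomial(60, 0.05) 99.9% upper bound
})

test_that("AIC model selection recovers the generating correlation structure", {
  set.seed(41)
  wins <- 0L
  reps <- 20L
  for (r in seq_len(reps)) {
    ma <- draw_ma(30)
    d <- make_model_responses(30, rho = 0.6, sigma = 5, ma = ma,
                              beta_snp = -3)
    specs <- lapply(c("AR1", "CS", "independent"), function(st)
      model_spec(structure = st))
    covars <- data.frame(subject = unique(d$subject))
    best <- select_model(specs, d, covars, ma)$best
    if (best$structure == "AR1") wins <- wins + 1L
  }
  expect_gte(wins, 18L)
  # single candidate returns unchanged
  one <- model_spec(structure = "CS")
  covars <- data.frame(subject = sprintf("S%03d", 1:30))
  set.seed(42)
  ma <- draw_ma(30)
  d <- make_model_responses(30, ma = ma)
  expect_identical(select_model(one, d, covars, ma)$best, one)
})

test_that("independent-error data do not spuriously favour AR1 by much", {
  set.seed(43)
  ok <- 0L
  for (r in 1:10) {
    ma <- draw_ma(25)
    d <- make_model_responses(25, rho = 0, sigma = 5, ma = ma)
    covars <- data.frame(subject = unique(d$subject))
    tab <- select_model(lapply(c("AR1", "independent"), function(st)
      model_spec(structure = st)), d, covars, ma)$table
    if (tab$AIC[tab$structure == "independent"] <=
        tab$AIC[tab$structure == "AR1"] + 2.1) ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})

test_that("partial PVE equals the R2 difference and is nonnegative", {
  set.seed(44)
  for (r in 1:5) {
    n <- 25
    ma <- draw_ma(n)
    d <- make_model_responses(n, ma = ma, beta_snp = runif(1, -8, 0))
    covars <- data.frame(subject = unique(d$subject),
                         age = rnorm(n, 45, 8))
    ff <- fit_final(model_spec(covariates = "age", interactions = TRUE),
                    d, covars, ma)
    expect_equal(ff$partial_pve, ff$r2_full - ff$r2_nosnp)
    expect_gte(ff$partial_pve, 0)
    expect_gte(ff$r2_full, 0); expect_lt(ff$r2_full, 1)
  }
})

test_that("null genotype has negligible partial PVE; planted share is recovered", {
  set.seed(45)
  pves <- replicate(12, {
    n <- 60
    ma <- draw_ma(n)
    d <- make_model_responses(n, ma = ma, beta_snp = 0)
    ff <- fit_final(model_spec(interactions = FALSE), d,
                    data.frame(subject = unique(d$subject)), ma)
    ff$partial_pve
  })
  expect_lt(median(pves), 0.01)
  # planted effect at rho = 0: with m hours per subject and subject-count n
  # in the exponent, the expected pseudo-R2 is 1 - (1 - share)^m where share
  # is the genotype's variance fraction at the observation level
  n <- 200; m <- 19
  ma <- draw_ma(n, 0.3)
  d <- make_model_responses(n, rho = 0, sigma = 6, ma = ma, beta_snp = -2)
  ff <- fit_final(model_spec(interactions = FALSE), d,
                  data.frame(subject = unique(d$subject)), ma)
  vg <- var(as.numeric(ma)) * 2^2
  expected <- 1 - (36 / (vg + 36))^m
  expect_lt(abs(ff$r2_full - expected), 0.08)
})

test_that("recessive and dominant codings collapse groups as defined", {
  ma <- c(a = 0, b = 1, c = 2, d = 1)
  expect_equal(pehscreen:::code_genotype(ma, "additive"), c(0, 1, 2, 1),
               ignore_attr = TRUE)
  expect_equal(pehscreen:::code_genotype(ma, "dominant"), c(0, 1, 1, 1),
               ignore_attr = TRUE)
  expect_equal(pehscreen:::code_genotype(ma, "recessive"), c(0, 0, 1, 0),
               ignore_attr = TRUE)
})

test_that("an n=1 genotype group flags a potential overfit", {
  set.seed(46)
  n <- 14
  ma <- setNames(c(rep(0L, 13), 1L), sprintf("S%03d", 1:n))
  d <- make_model_responses(n, ma = ma, beta_snp = -25)
  ff <- fit_final(model_spec(interactions = FALSE), d,
                  data.frame(subject = unique(d$subject)), ma)
  expect_true(ff$overfit_flag)
})
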