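# Phenotype construction: QC rules, completeness, hourly aggregation, the
# exercise-minus-control response, AASI, and descriptive summaries.

test_that("QC removes exactly the out-of-range readings, with strict bounds", {
  r <- data.frame(sbp = c(225, 220, 120, 79.9, 80, 150),
                  dbp = c(90, 130, 39, 70, 40, 131))
  kept <- qc_readings(r)
  # removed: sbp 225; dbp 39; sbp 79.9; dbp 131. boundary 220/130 and 80/40 stay
  expect_equal(kept$sbp, c(220, 80))
  expect_identical(qc_readings(kept), kept)          # idempotent
  expect_equal(nrow(qc_readings(r[0, ])), 0L)
})

test_that("completeness rule is >= 80% of potential readings", {
  expect_true(completeness_ok(40, 50))
  expect_false(completeness_ok(39, 50))
  expect_true(completeness_ok(50, 50))
  expect_error(completeness_ok(10, 0), "> 0")
})

test_that("hourly aggregation bins half-open hours and subtracts baseline", {
  base <- data.frame(sbp = rep(120, 10), dbp = rep(80, 10))
  r <- data.frame(timestamp_min = c(0, 30, 59.9, 60, 90), sbp = 120 + 5,
                  dbp = 80 + 5)
  agg <- hourly_aggregate(r, base, hours = 1:3)
  expect_equal(agg$sbp_change, c(5, 5, NA_real_))
  expect_equal(agg$dbp_change, c(5, 5, NA_real_))
  # shift equivariance
  r2 <- r; r2$sbp <- r2$sbp + 7
  agg2 <- hourly_aggregate(r2, base, hours = 1:3)
  expect_equal(agg2$sbp_change, agg$sbp_change + 7)
  expect_error(hourly_aggregate(r, base[0, ]), "baseline")
})

test_that("response is exercise minus control change, antisymmetric and linear", {
  base <- data.frame(sbp = rep(120, 5), dbp = rep(80, 5))
  mk <- function(shift) {
    r <- data.frame(timestamp_min = seq(5, 1135, by = 20),
                    sbp = 120 + shift, dbp = 80 + shift / 2)
    hourly_aggregate(r, base)
  }
  ctrl <- mk(0); ex <- mk(-10)
  resp <- compute_response(ex, ctrl, "s1")
  expect_equal(resp$sbp, rep(-10, 19))
  expect_equal(compute_response(ex, ex)$sbp, rep(0, 19))        # identity
  swapped <- compute_response(ctrl, ex)
  expect_equal(swapped$sbp, -resp$sbp)                          # antisymmetry
  ex2 <- ex; ex2$sbp_change <- ex2$sbp_change + 3               # linearity
  expect_equal(compute_response(ex2, ctrl)$sbp, resp$sbp + 3)
})

test_that("AASI closed forms: identity slope, flat DBP, 3-point OLS", {
  s <- seq(100, 140, by = 2)
  expect_equal(compute_aasi(data.frame(sbp = s, dbp = s)), 0)
  expect_equal(compute_aasi(data.frame(sbp = s, dbp = rep(70, length(s)))), 1)
  r3 <- data.frame(sbp = c(100, 120, 140), dbp = c(60, 70, 80))
  expect_equal(compute_aasi(r3), 0.5)
  expect_error(compute_aasi(data.frame(sbp = rep(1, 5), dbp = 1:5)),
               "variance")
})

test_that("hourly means track the latent trajectory of a synthetic session", {
  cfg <- simulation_config(n_subjects = c(AF = 4L), artifact_rate = 0,
                           missing_rate = 0, reading_sd = 2, seed = 3)
  ch <- simulate_cohort(cfg, sessions = c("CONTROL", "VIGOROUS"))
  sid <- ch$subjects$subject[1]
  r <- ch$readings[ch$readings$subject == sid &
                   ch$readings$session == "VIGOROUS", ]
  b <- ch$baseline[ch$baseline$subject == sid &
                   ch$baseline$session == "VIGOROUS", ]
  agg <- hourly_aggregate(qc_readings(r), b)
  lat <- ch$latent[ch$latent$subject == sid & ch$latent$session == "VIGOROUS", ]
  # hourly mean of 2-3 readings with SD-2 noise, minus a 10-reading baseline
  se <- 2 / sqrt(2) + 2 / sqrt(10)
  expect_lt(max(abs(agg$sbp_change - (lat$sbp + ch$subjects$baseline_sbp[1] -
                                      mean(b$sbp)) -
                    (mean(b$sbp) - ch$subjects$baseline_sbp[1]) * 0)), 6 * se)
  expect_gt(cor(agg$sbp_change, lat$sbp), 0.95)
})

test_that("group summary reproduces means/SDs and handles n=1 groups", {
  set.seed(8)
  vals <- c(a = 2, b = 4, c = 9, d = -5)
  resp <- do.call(rbind, lapply(names(vals), function(s)
    data.frame(subject = s, hour = 1:19, sbp = vals[[s]], dbp = vals[[s]] / 2)))
  ma <- c(a = 0, b = 0, c = 1, d = 2)
  gs <- genotype_group_summary(resp, ma)
  expect_equal(gs$groups$n, c(2L, 1L, 1L))
  expect_equal(gs$groups$sbp_mean, c(3, 9, -5))
  expect_equal(gs$groups$sbp_sd, c(sd(c(2, 4)), NA, NA))
  expect_equal(gs$contrasts$sbp, c(6, -8))
  # identical responses: zero contrasts
  resp0 <- resp; resp0$sbp <- 1; resp0$dbp <- 1
  gs0 <- genotype_group_summary(resp0, ma)
  expect_equal(gs0$contrasts$sbp, c(0, 0))
  expect_error(genotype_group_summary(resp, ma[-1]), "missing genotype")
})

test_that("cohort descriptives: identical groups give t = 0, separation is detected", {
  prof <- data.frame(ethnicity = rep(c("A", "B"), each = 3),
                     x = c(1, 2, 3, 1, 2, 3),
                     y = c(0, 0, 0.001, 1, 1, 1.001))
  d <- describe_cohort(prof, "ethnicity", c("x", "y"))
  expect_equal(d$t[d$covariate == "x"], 0)
  expect_equal(d$p[d$covariate == "x"], 1)
  expect_lt(d$p[d$covariate == "y"], 0.001)
  prof$z <- 1
  dz <- describe_cohort(prof, "ethnicity", "z")
  expect_true(dz$degenerate)
  expect_true(is.na(dz$p))
})

test_that("subject 19-h average equals difference of session averages", {
  set.seed(9)
  base <- data.frame(sbp = rnorm(10, 120), dbp = rnorm(10, 80))
  r1 <- data.frame(timestamp_min = seq(1, 1139, by = 12),
                   sbp = rnorm(95, 125, 5), dbp = rnorm(95, 82, 4))
  r2 <- data.frame(timestamp_min = seq(1, 1139, by = 12),
                   sbp = rnorm(95, 118, 5), dbp = rnorm(95, 79, 4))
  ex <- hourly_aggregate(r1, base); ctrl <- hourly_aggregate(r2, base)
  resp <- compute_response(ex, ctrl)
  expect_equal(mean(resp$sbp), mean(ex$sbp_change) - mean(ctrl$sbp_change))
})
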