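# Synthetic-data generator: genotype sampling, AR1 structure of the latent
# responses, artifact/missingness injection, file round trips, determinism.

test_that("genotype sampling respects degenerate and binomial frequencies", {
  v <- default_variant_panel("G", 3)
  v$maf_G <- c(0, 1, 0.3)
  cfg <- simulation_config(n_subjects = c(G = 400L), variants = v, seed = 2)
  G <- simulate_genotypes(cfg)
  expect_true(all(G[, 1] == 0))
  expect_true(all(G[, 2] == 2))
  phat <- mean(G[, 3]) / 2
  se <- sqrt(0.3 * 0.7 / (2 * 400))
  expect_lt(abs(phat - 0.3), 3 * se)
  v$maf_G[1] <- 1.2
  expect_error(simulation_config(n_subjects = c(G = 5L), variants = v),
               "maf_G")
})

test_that("latent responses carry the configured AR1 correlation", {
  set.seed(10)
  cfg <- simulation_config(n_subjects = c(G = 150L),
                           variants = default_variant_panel("G", 2),
                           rho = 0.6, sigma = 5, seed = 11)
  ch <- simulate_cohort(cfg, sessions = c("CONTROL", "VIGOROUS"))
  lat <- ch$latent[ch$latent$session == "VIGOROUS", ]
  s <- split(lat$sbp, lat$subject)
  num <- sum(vapply(s, function(v) sum(v[-1] * v[-length(v)]), numeric(1)))
  den <- sum(vapply(s, function(v) sum(v[-length(v)]^2), numeric(1)))
  expect_lt(abs(num / den - 0.6), 0.05)
  vv <- vapply(s, var, numeric(1))
  expect_lt(abs(mean(vv) - 25), 5)
})

test_that("null generator produces mean response near zero; effects are additive", {
  eff <- data.frame(id = "var01", intensity = "VIGOROUS", outcome = "sbp",
                    beta = -10, d1 = 0, d2 = 0, d3 = 0)
  cfg <- simulation_config(n_subjects = c(G = 300L),
                           variants = default_variant_panel("G", 2),
                           effects = eff, rho = 0, sigma = 5,
                           artifact_rate = 0, missing_rate = 0, seed = 12)
  ch <- simulate_cohort(cfg, sessions = c("CONTROL", "VIGOROUS"))
  lat <- ch$latent[ch$latent$session == "VIGOROUS", ]
  subj_mean <- tapply(lat$sbp, lat$subject, mean)
  g <- ch$genotypes[names(subj_mean), "var01"]
  m2 <- mean(subj_mean[g == 2]); m0 <- mean(subj_mean[g == 0])
  expect_lt(abs((m2 - m0) - (-20)), 2.5)        # linear in #MA
  # dbp latent of the same subjects has no injected effect
  dmean <- tapply(lat$dbp, lat$subject, mean)
  expect_lt(abs(mean(dmean)), 3 * 5 / sqrt(300))
})

test_that("writing and ingesting a cohort round-trips the genotype matrix", {
  cfg <- simulation_config(n_subjects = c(AF = 12L, CAU = 8L), seed = 13)
  ch <- simulate_cohort(cfg, sessions = "CONTROL")
  dir <- withr::local_tempdir()
  paths <- write_cohort(ch, dir, nonpass_decoys = 3L)
  gm <- ingest_vcf(paths$vcf, samples = rownames(ch$genotypes))
  expect_equal(ncol(gm$geno), ncol(ch$genotypes))   # decoys filtered out
  expect_false(any(grepl("decoy", colnames(gm$geno))))
  expect_equal(unname(gm$geno[, colnames(ch$genotypes)]),
               unname(ch$genotypes))
  # determinism: regenerating with the same seed is bit-identical
  ch2 <- simulate_cohort(cfg, sessions = "CONTROL")
  expect_identical(ch$genotypes, ch2$genotypes)
  expect_identical(ch$readings, ch2$readings)
})

test_that("artifact injection produces out-of-range readings QC removes", {
  cfg <- simulation_config(n_subjects = c(G = 30L),
                           variants = default_variant_panel("G", 2),
                           artifact_rate = 0.15, missing_rate = 0, seed = 14)
  ch <- simulate_cohort(cfg, sessions = c("CONTROL", "VIGOROUS"))
  kept <- qc_readings(ch$readings)
  frac_removed <- 1 - nrow(kept) / nrow(ch$readings)
  expect_gt(frac_removed, 0.10)
  expect_lt(frac_removed, 0.20)
  expect_true(all(kept$sbp <= 220 & kept$sbp >= 80 &
                  kept$dbp <= 130 & kept$dbp >= 40))
})

test_that("screening recovers the genotype effect from the raw-readings path", {
  eff <- data.frame(id = "var01", intensity = "VIGOROUS", outcome = "sbp",
                    beta = -8, d1 = 0, d2 = 0, d3 = 0)
  cfg <- simulation_config(n_subjects = c(G = 200L),
                           variants = default_variant_panel("G", 2),
                           effects = eff, rho = 0.5, sigma = 6,
                           artifact_rate = 0, missing_rate = 0, seed = 15)
  ch <- simulate_cohort(cfg, sessions = c("CONTROL", "VIGOROUS"))
  resp <- build_response_series(ch$readings, ch$baseline, "VIGOROUS")
  ma <- ch$genotypes[, "var01"]
  des <- ar1_design(resp, ma, "sbp", interactions = FALSE)
  f <- fit_ar1(des$y, des$X_full, des$subject, des$time)
  expect_lt(abs(coef(f)["snp"] + 8), 2 * f$se["snp"] + 0.3)
})
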