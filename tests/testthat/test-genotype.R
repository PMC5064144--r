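# VCF ingest, minor-allele coding, amplicon summaries, profile universe.

test_that("GT fields code directly to minor-allele counts when ALT is minor", {
  path <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"),
                        list(c("0/0", "0/1", "1/1", "0/1", "0/0")))
  gm <- ingest_vcf(path)
  expect_equal(unname(gm$geno[, 1]), c(0L, 1L, 2L, 1L, 0L))
  expect_true(gm$variants$minor_is_alt)
})

test_that("common ALT alleles are recoded so the count refers to the minor allele", {
  # ALT frequency 7/10: REF is minor; 1/1 carries 0 minor alleles
  path <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"),
                        list(c("1/1", "1/1", "1/1", "0/1", "0/0")))
  gm <- ingest_vcf(path)
  expect_equal(unname(gm$geno[, 1]), c(0L, 0L, 0L, 1L, 2L))
  expect_false(gm$variants$minor_is_alt)
  expect_equal(gm$variants$maf, 0.3)
})

test_that("non-PASS records are dropped and missing samples are an error", {
  path <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"),
                        list(c("0/0", "0/1", "1/1", "0/1", "0/0"),
                             c("0/1", "0/0", "0/0", "0/0", "0/0")),
                        filters = c("LowQual", "PASS"))
  gm <- ingest_vcf(path)
  expect_equal(ncol(gm$geno), 1L)
  expect_equal(colnames(gm$geno), "rs2")
  expect_error(ingest_vcf(path, samples = c("S1", "S99")), "S99")
})

test_that("multi-allelic sites split into biallelic records with per-ALT counts", {
  path <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"),
                        list(c("0/1", "1/2", "2/2", "0/0", "./.")),
                        multi = TRUE)
  gm <- ingest_vcf(path)
  expect_equal(ncol(gm$geno), 2L)
  expect_equal(unname(gm$geno[, 1]), c(1L, 1L, 0L, 0L, NA))   # allele 1
  expect_equal(unname(gm$geno[, 2]), c(0L, 1L, 2L, 0L, NA))   # allele 2
})

test_that("amplicon summaries match a brute-force tally", {
  set.seed(20)
  cfg <- simulation_config(n_subjects = c(AF = 10L, CAU = 10L), seed = 21)
  ch <- simulate_cohort(cfg, sessions = "CONTROL")
  dir <- withr::local_tempdir()
  paths <- write_cohort(ch, dir)
  gm <- ingest_vcf(paths$vcf)
  man <- read.delim(paths$manifest)
  s <- amplicon_summaries(gm, man)
  # brute force per cell
  for (a in colnames(s$per_subject)) {
    cols <- which(!is.na(s$per_variant$amplicon) & s$per_variant$amplicon == a)
    for (i in seq_len(nrow(gm$geno))) {
      expect_equal(s$per_subject[i, a],
                   sum(gm$geno[i, cols] >= 1, na.rm = TRUE))
    }
  }
  expect_equal(unname(s$per_variant$maf),
               unname(colSums(gm$geno) / (2 * nrow(gm$geno))))
  # all-zero matrix
  gm0 <- gm; gm0$geno[] <- 0L
  s0 <- amplicon_summaries(gm0, man)
  expect_true(all(s0$per_subject == 0))
  expect_true(all(s0$per_variant$maf == 0))
})

test_that("profile universe counts distinct variable columns", {
  M <- cbind(a = c(0, 1, 2, 0), b = c(0, 1, 2, 0), c = c(1, 1, 1, 1),
             d = c(0, 0, 1, 2), e = c(0, 1, 2, 0))
  rownames(M) <- paste0("S", 1:4)
  u <- build_profile_universe(M)
  expect_equal(u$K, 2L)                       # {a,b,e} share, d distinct, c mono
  expect_true(is.na(u$profile["c"]))
  expect_equal(u$profile[["a"]], u$profile[["b"]])
  expect_equal(u$profile[["a"]], u$profile[["e"]])
  # invariant to permutation and duplication
  u2 <- build_profile_universe(M[, c("d", "e", "a", "c", "b")])
  expect_equal(u2$K, 2L)
  u3 <- build_profile_universe(cbind(M, f = M[, "d"]))
  expect_equal(u3$K, 2L)
  expect_error(build_profile_universe(M[, "c", drop = FALSE]), "monomorphic")
})

test_that("random matrices: K equals the set-of-tuples count, per subgroup", {
  set.seed(22)
  for (rep in 1:5) {
    M <- matrix(sample(0:2, 8 * 12, replace = TRUE, prob = c(0.6, 0.3, 0.1)),
                8, 12, dimnames = list(paste0("S", 1:8), paste0("v", 1:12)))
    M[, 4] <- M[, 2]                               # planted duplicate
    sub <- paste0("S", 1:5)                        # subgroup restriction
    Ms <- M[sub, ]
    variable <- apply(Ms, 2, function(x) length(unique(x)) > 1)
    expected <- length(unique(apply(Ms[, variable, drop = FALSE], 2, paste,
                                    collapse = ",")))
    if (!any(variable)) next
    expect_equal(build_profile_universe(M, sub)$K, expected)
  }
})
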