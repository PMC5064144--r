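# Synthetic study generator: cohort covariates, per-ethnicity genotypes,
# and raw ambulatory BP readings whose hourly structure matches the screening
# model (cubic time trend + additive genotype effects + AR1 noise).

#' Simulation configuration for a synthetic postexercise-hypotension study
#'
#' Encodes the generative counterpart of the screening model: a cubic
#' polynomial time trend, per-variant additive genotype effects (main effect
#' in mmHg per minor allele plus genotype-by-time interaction coefficients),
#' and within-subject AR1 Gaussian noise around the latent hourly response.
#' Defaults mirror the study design the package emulates: two ethnic groups
#' of 14 and 9 subjects, 19 monitored hours with three readings per waking
#' hour and two per sleep hour, and a 20-minute pre-session baseline series.
#'
#' @param n_subjects named integer vector, subjects per ethnicity label.
#' @param variants data frame with columns \code{id}, \code{gene},
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt} and one minor-allele
#'   frequency column \code{maf_<label>} per ethnicity.
#' @param effects data frame of non-null genotype effects with columns
#'   \code{id}, \code{intensity}, \code{outcome} (\code{"sbp"}/\code{"dbp"}),
#'   \code{beta} (mmHg per minor allele) and interaction coefficients
#'   \code{d1}, \code{d2}, \code{d3} on centered time, its square and cube.
#'   Variants absent from the table have no effect.
#' @param time_trend length-4 numeric: population intercept and centered-time
#'   polynomial coefficients of the latent response (shared by intensities).
#' @param time_points monitored hours per session (default 19).
#' @param sigma residual SD of the latent hourly response, mmHg.
#' @param rho within-subject lag-1 autocorrelation, in (-1, 1).
#' @param reading_sd SD of independent measurement noise per raw reading.
#' @param baseline_sbp_mean,baseline_sbp_sd,baseline_dbp_mean,baseline_dbp_sd
#'   between-subject distribution of resting BP, mmHg.
#' @param artifact_rate probability a raw reading is replaced by an
#'   out-of-range artifact (removed by downstream QC).
#' @param missing_rate probability a raw reading is absent.
#' @param wake_hours,sleep_hours partition of hours 1..time_points; waking
#'   hours yield 3 readings, sleep hours 2.
#' @param dbp_scale ratio of DBP to SBP latent response when no explicit DBP
#'   effect row is given (population trend only).
#' @param seed master integer seed; per-subject substreams are derived from
#'   it so subsetting the cohort is reproducible.
#' @return a validated list of class \code{sim_config}.
#' @export
simulation_config <- function(n_subjects = c(AF = 14L, CAU = 9L),
                              variants = default_variant_panel(names(n_subjects)),
                              effects = NULL,
                              time_trend = c(0, 0, 0, 0),
                              time_points = 19L,
                              sigma = 9, rho = 0.6, reading_sd = 3,
                              baseline_sbp_mean = 135, baseline_sbp_sd = 10,
                              baseline_dbp_mean = 82, baseline_dbp_sd = 7,
                              artifact_rate = 0.02, missing_rate = 0.02,
                              wake_hours = 1:13, sleep_hours = 14:19,
                              dbp_scale = 0.6, seed = 1L) {
  stopifnot(length(n_subjects) >= 1, !is.null(names(n_subjects)),
            all(n_subjects >= 1), time_points >= 2, sigma > 0,
            abs(rho) < 1, length(time_trend) == 4)
  assert_prob(artifact_rate, "artifact_rate")
  assert_prob(missing_rate, "missing_rate")
  maf_cols <- paste0("maf_", names(n_subjects))
  if (!all(maf_cols %in% names(variants)))
    stop("variants table must carry columns: ", paste(maf_cols, collapse = ", "))
  for (mc in maf_cols) assert_prob(variants[[mc]], mc)
  if (is.null(effects))
    effects <- data.frame(id = character(), intensity = character(),
                          outcome = character(), beta = numeric(),
                          d1 = numeric(), d2 = numeric(), d3 = numeric())
  stopifnot(all(c("id", "intensity", "outcome", "beta") %in% names(effects)))
  for (d in c("d1", "d2", "d3")) if (is.null(effects[[d]])) effects[[d]] <- 0
  stopifnot(all(sort(c(wake_hours, sleep_hours)) == seq_len(time_points)))
  structure(list(
    n_subjects = n_subjects, ethnicities = names(n_subjects),
    variants = variants, effects = effects, time_trend = time_trend,
    time_points = as.integer(time_points), sigma = sigma, rho = rho,
    reading_sd = reading_sd,
    baseline_sbp_mean = baseline_sbp_mean, baseline_sbp_sd = baseline_sbp_sd,
    baseline_dbp_mean = baseline_dbp_mean, baseline_dbp_sd = baseline_dbp_sd,
    artifact_rate = artifact_rate, missing_rate = missing_rate,
    wake_hours = wake_hours, sleep_hours = sleep_hours,
    dbp_scale = dbp_scale, seed = as.integer(seed)), class = "sim_config")
}

#' Default synthetic variant panel
#'
#' A small panel over four renin-angiotensin / renal genes with per-ethnicity
#' minor-allele frequencies; positions are synthetic amplicon coordinates.
#' @param labels ethnicity labels needing \code{maf_<label>} columns.
#' @param n_variants number of variants.
#' @return variant specification data frame.
#' @export
default_variant_panel <- function(labels = c("AF", "CAU"), n_variants = 12L) {
  genes <- c("ACE", "AGTR1", "CYP11B2", "ADD1")
  g <- rep(genes, length.out = n_variants)
  v <- data.frame(
    id = sprintf("var%02d", seq_len(n_variants)),
    gene = g,
    chrom = c(ACE = "chr17", AGTR1 = "chr3", CYP11B2 = "chr8", ADD1 = "chr4")[g],
    pos = 10000L + 250L * seq_len(n_variants),
    ref = rep(c("A", "C", "G", "T"), length.out = n_variants),
    alt = rep(c("G", "T", "A", "C"), length.out = n_variants),
    stringsAsFactors = FALSE)
  base_maf <- rep(c(0.10, 0.25, 0.35, 0.15), length.out = n_variants)
  for (lab in labels) {
    v[[paste0("maf_", lab)]] <- base_maf
    base_maf <- rev(base_maf)  # mild ethnic differentiation
  }
  v
}

#' Draw genotypes as minor-allele counts
#'
#' Each entry is Binomial(2, MAF) for the subject's ethnicity: Hardy-Weinberg
#' sampling of the number of minor alleles.
#'
#' @param config a \code{sim_config}.
#' @return integer matrix subjects x variants with dimnames; values 0/1/2.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  subj <- subject_table(config)
  set.seed(substream_seed(config$seed, 1L))
  G <- matrix(0L, nrow(subj), nrow(config$variants),
              dimnames = list(subj$subject, config$variants$id))
  for (e in config$ethnicities) {
    rows <- which(subj$ethnicity == e)
    maf <- config$variants[[paste0("maf_", e)]]
    for (j in seq_len(nrow(config$variants)))
      G[rows, j] <- stats::rbinom(length(rows), 2L, maf[j])
  }
  G
}

subject_table <- function(config) {
  ids <- sprintf("S%03d", seq_len(sum(config$n_subjects)))
  data.frame(subject = ids,
             ethnicity = rep(config$ethnicities, config$n_subjects),
             stringsAsFactors = FALSE)
}

# AR1 Gaussian noise series: stationary start, innovations recursion.
r_ar1_noise <- function(m, rho, sigma) {
  e <- numeric(m)
  e[1L] <- stats::rnorm(1L, 0, sigma)
  if (m > 1L) {
    innov <- stats::rnorm(m - 1L, 0, sigma * sqrt(1 - rho^2))
    for (t in 2:m) e[t] <- rho * e[t - 1L] + innov[t - 1L]
  }
  e
}

latent_response <- function(config, ma_row, intensity, outcome, hours) {
  tc <- hours - 10                       # centered at hour 10
  Xt <- cbind(1, tc, tc^2, tc^3)
  mu <- as.vector(Xt %*% config$time_trend)
  if (outcome == "dbp") mu <- mu * config$dbp_scale
  ef <- config$effects
  ef <- ef[ef$intensity == intensity & ef$outcome == outcome, , drop = FALSE]
  if (nrow(ef)) for (k in seq_len(nrow(ef))) {
    ma <- ma_row[[ef$id[k]]]
    if (is.null(ma) || is.na(ma)) next
    mu <- mu + ma * as.vector(Xt %*% c(ef$beta[k], ef$d1[k], ef$d2[k], ef$d3[k]))
  }
  mu
}

#' Simulate a complete synthetic cohort
#'
#' Generates subjects with covariates, genotypes, and per-session raw
#' ambulatory readings, retaining the latent hourly responses and the effect
#' specification actually used (ground truth for recovery tests).
#'
#' @param config a \code{sim_config}.
#' @param sessions sessions to generate; CONTROL is always included.
#' @return list of class \code{sim_cohort}: \code{subjects}, \code{genotypes},
#'   \code{readings}, \code{baseline}, \code{latent}, \code{truth},
#'   \code{config}.
#' @export
simulate_cohort <- function(config,
                            sessions = c("CONTROL", "MODERATE", "VIGOROUS")) {
  stopifnot(inherits(config, "sim_config"))
  sessions <- union("CONTROL", sessions)
  subj <- subject_table(config)
  set.seed(substream_seed(config$seed, 2L))
  n <- nrow(subj)
  subj$age <- round(stats::rnorm(n, 42, 9), 1)
  subj$sex <- stats::rbinom(n, 1L, 0.7)                 # 1 = male
  subj$bmi <- round(stats::rnorm(n, 31, 3.5), 1)
  subj$insulin <- round(stats::rlnorm(n, log(12), 0.45), 2)
  subj$triglycerides <- round(stats::rlnorm(n, log(115), 0.35), 1)
  subj$endothelin <- round(stats::rlnorm(n, log(1.6), 0.30), 3)
  subj$baseline_sbp <- stats::rnorm(n, config$baseline_sbp_mean,
                                    config$baseline_sbp_sd)
  subj$baseline_dbp <- stats::rnorm(n, config$baseline_dbp_mean,
                                    config$baseline_dbp_sd)
  geno <- simulate_genotypes(config)
  bp <- simulate_bp_sessions(subj, geno, config, sessions)
  structure(list(subjects = subj, genotypes = geno,
                 readings = bp$readings, baseline = bp$baseline,
                 latent = bp$latent, truth = config$effects, config = config),
            class = "sim_cohort")
}

#' Simulate raw ambulatory readings for every subject and session
#'
#' The latent hourly response of an exercise session is the cubic time trend
#' plus genotype effects plus an AR1(\eqn{\rho}, \eqn{\sigma^2}) series; the
#' control session is flat at the subject's resting BP, so the derived
#' response phenotype (exercise change minus control change) recovers the
#' latent series up to reading noise. Raw readings add independent Gaussian
#' measurement noise (3 per waking hour, 2 per sleep hour); artifacts are
#' drawn uniformly from the QC exclusion ranges; readings are dropped at the
#' configured missingness rate. Each session also gets a 10-reading baseline
#' series (every 2 min for 20 min before the session).
#'
#' @param subjects subject table with \code{baseline_sbp}/\code{baseline_dbp}.
#' @param geno genotype matrix (subjects x variants).
#' @param config a \code{sim_config}.
#' @param sessions character vector of sessions.
#' @return list with long data frames \code{readings} (subject, session,
#'   timestamp_min, sbp, dbp, state), \code{baseline}, and \code{latent}
#'   (subject, session, hour, sbp, dbp).
#' @export
simulate_bp_sessions <- function(subjects, geno, config,
                                 sessions = c("CONTROL", "MODERATE", "VIGOROUS")) {
  hours <- seq_len(config$time_points)
  state <- ifelse(hours %in% config$wake_hours, "wake", "sleep")
  nper <- ifelse(state == "wake", 3L, 2L)
  offsets <- list(`3` = c(10, 30, 50), `2` = c(15, 45))
  out_r <- vector("list", nrow(subjects) * length(sessions))
  out_b <- vector("list", length(out_r))
  out_l <- vector("list", length(out_r))
  k <- 0L
  for (i in seq_len(nrow(subjects))) {
    set.seed(substream_seed(config$seed, 100L + i))
    sid <- subjects$subject[i]
    for (ses in sessions) {
      k <- k + 1L
      resp_sbp <- if (ses == "CONTROL") numeric(config$time_points) else
        latent_response(config, as.list(geno[sid, , drop = TRUE]), ses, "sbp", hours) +
        r_ar1_noise(config$time_points, config$rho, config$sigma)
      resp_dbp <- if (ses == "CONTROL") numeric(config$time_points) else
        latent_response(config, as.list(geno[sid, , drop = TRUE]), ses, "dbp", hours) +
        r_ar1_noise(config$time_points, config$rho, config$sigma * config$dbp_scale)
      lat_sbp <- subjects$baseline_sbp[i] + resp_sbp
      lat_dbp <- subjects$baseline_dbp[i] + resp_dbp
      # raw ambulatory readings
      hh <- rep(hours, nper)
      ts <- 60 * (hh - 1) + unlist(lapply(nper, function(np) offsets[[as.character(np)]]))
      rs <- stats::rnorm(length(ts), lat_sbp[hh], config$reading_sd)
      rd <- stats::rnorm(length(ts), lat_dbp[hh], config$reading_sd)
      art <- stats::runif(length(ts)) < config$artifact_rate
      if (any(art)) {
        which_art <- which(art)
        kind <- sample(4L, length(which_art), replace = TRUE)
        rs[which_art][kind == 1L] <- stats::runif(sum(kind == 1L), 220.1, 260)
        rs[which_art][kind == 2L] <- stats::runif(sum(kind == 2L), 40, 79.9)
        rd[which_art][kind == 3L] <- stats::runif(sum(kind == 3L), 130.1, 160)
        rd[which_art][kind == 4L] <- stats::runif(sum(kind == 4L), 20, 39.9)
      }
      keep <- stats::runif(length(ts)) >= config$missing_rate
      out_r[[k]] <- data.frame(subject = sid, session = ses,
                               timestamp_min = ts[keep],
                               sbp = round(rs[keep], 1), dbp = round(rd[keep], 1),
                               state = rep(state, nper)[keep],
                               stringsAsFactors = FALSE)
      bts <- seq(-20, -2, by = 2)
      out_b[[k]] <- data.frame(subject = sid, session = ses,
                               timestamp_min = bts,
                               sbp = round(stats::rnorm(length(bts), subjects$baseline_sbp[i],
                                                        config$reading_sd), 1),
                               dbp = round(stats::rnorm(length(bts), subjects$baseline_dbp[i],
                                                        config$reading_sd), 1),
                               stringsAsFactors = FALSE)
      out_l[[k]] <- data.frame(subject = sid, session = ses, hour = hours,
                               sbp = resp_sbp, dbp = resp_dbp,
                               stringsAsFactors = FALSE)
    }
  }
  list(readings = do.call(rbind, out_r), baseline = do.call(rbind, out_b),
       latent = do.call(rbind, out_l))
}

gt_string <- function(count) c("0/0", "0/1", "1/1")[count + 1L]

#' Write a simulated cohort to disk
#'
#' Serializes genotypes as a multi-sample VCF v4.2 (GT format, FILTER=PASS;
#' optional decoy records with FILTER=LowQual to exercise downstream
#' filtering), readings/baseline/covariates as tab-delimited text, plus an
#' amplicon manifest covering the panel and the ground-truth effect table.
#' ALT is always written as the cohort minor allele, so a round trip through
#' \code{\link{ingest_vcf}} reproduces the minor-allele-count matrix exactly.
#'
#' @param cohort a \code{sim_cohort}.
#' @param dir output directory (created if needed).
#' @param nonpass_decoys number of additional non-PASS records to write.
#' @return invisibly, a named list of file paths.
#' @export
write_cohort <- function(cohort, dir, nonpass_decoys = 0L) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(vcf = file.path(dir, "genotypes.vcf"),
                covariates = file.path(dir, "covariates.tsv"),
                readings = file.path(dir, "readings.tsv"),
                baseline = file.path(dir, "baseline.tsv"),
                manifest = file.path(dir, "amplicons.tsv"),
                truth = file.path(dir, "truth.tsv"))
  v <- cohort$config$variants
  G <- cohort$genotypes
  samples <- rownames(G)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=pehscreen-synthetic-cohort",
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
           "##FILTER=<ID=LowQual,Description=\"Synthetic low-quality decoy\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- character(0)
  for (j in seq_len(nrow(v))) {
    ma <- G[, j]
    flip <- mean(ma) / 2 > 0.5          # ensure ALT is the cohort minor allele
    alt_counts <- if (flip) 2L - ma else ma
    ref <- if (flip) v$alt[j] else v$ref[j]
    alt <- if (flip) v$ref[j] else v$alt[j]
    body <- c(body, paste(c(v$chrom[j], v$pos[j], v$id[j], ref, alt, "100",
                            "PASS", paste0("GENE=", v$gene[j]), "GT",
                            gt_string(alt_counts)), collapse = "\t"))
  }
  if (nonpass_decoys > 0L) {
    set.seed(substream_seed(cohort$config$seed, 7L))
    for (d in seq_len(nonpass_decoys)) {
      counts <- stats::rbinom(length(samples), 2L, 0.2)
      body <- c(body, paste(c("chr9", 5000L + 50L * d, sprintf("decoy%02d", d),
                              "A", "T", "10", "LowQual", "GENE=DECOY", "GT",
                              gt_string(counts)), collapse = "\t"))
    }
  }
  writeLines(c(hdr, body), paths$vcf)
  utils::write.table(cohort$subjects, paths$covariates, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$readings, paths$readings, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$baseline, paths$baseline, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  man <- do.call(rbind, lapply(split(v, v$gene), function(g)
    data.frame(target_id = paste0("AMP_", g$gene[1]), chrom = g$chrom[1],
               start = min(g$pos) - 50L, end = max(g$pos) + 50L,
               stringsAsFactors = FALSE)))
  utils::write.table(man[order(man$target_id), ], paths$manifest, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, paths$truth, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
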