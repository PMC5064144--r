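# Orchestration: synthetic-data generation (or file ingest), phenotype
# construction, genotype coding, screening, final models, and power, driven
# by a single configuration with one master seed.

#' Validate pipeline inputs
#'
#' Checks VCF/sample-manifest concordance, the readings and baseline table
#' schemas, and covariate completeness. Problems are returned as diagnostics,
#' never raised.
#'
#' @param paths named list with any of \code{vcf}, \code{covariates},
#'   \code{readings}, \code{baseline} file paths.
#' @return data frame of diagnostics: \code{class}, \code{message}; zero
#'   rows when everything checks out.
#' @export
validate_inputs <- function(paths) {
  diag <- list()
  note <- function(class, message)
    diag[[length(diag) + 1L]] <<- data.frame(class = class, message = message,
                                             stringsAsFactors = FALSE)
  need <- function(p) !is.null(p) && file.exists(p)
  readings <- covs <- NULL
  if (!is.null(paths$readings)) {
    if (!need(paths$readings)) note("missing-file", paths$readings)
    else {
      readings <- utils::read.delim(paths$readings, stringsAsFactors = FALSE)
      want <- c("subject", "session", "timestamp_min", "sbp", "dbp")
      miss <- setdiff(want, names(readings))
      if (length(miss))
        note("schema", paste("readings table lacks column(s):",
                             paste(miss, collapse = ", ")))
    }
  }
  if (!is.null(paths$baseline)) {
    if (!need(paths$baseline)) note("missing-file", paths$baseline)
    else {
      b <- utils::read.delim(paths$baseline, stringsAsFactors = FALSE)
      miss <- setdiff(c("subject", "session", "sbp", "dbp"), names(b))
      if (length(miss))
        note("schema", paste("baseline table lacks column(s):",
                             paste(miss, collapse = ", ")))
    }
  }
  if (!is.null(paths$covariates)) {
    if (!need(paths$covariates)) note("missing-file", paths$covariates)
    else {
      covs <- utils::read.delim(paths$covariates, stringsAsFactors = FALSE)
      if (!"subject" %in% names(covs))
        note("schema", "covariate table lacks a 'subject' column")
      else if (!is.null(readings) && "subject" %in% names(readings)) {
        orphans <- setdiff(unique(readings$subject), covs$subject)
        for (s in orphans)
          note("covariate-missing", paste("subject", s, "has readings but no covariates"))
      }
    }
  }
  if (!is.null(paths$vcf)) {
    if (!need(paths$vcf)) note("missing-file", paths$vcf)
    else if (!is.null(covs) && "subject" %in% names(covs)) {
      hdr <- grep("^#CHROM", readLines(paths$vcf, n = 200L), value = TRUE)
      if (!length(hdr)) note("vcf-malformed", "no #CHROM header line found")
      else {
        vs <- strsplit(hdr[1L], "\t")[[1L]][-(1:9)]
        for (s in setdiff(vs, covs$subject))
          note("sample-mismatch", paste("VCF sample", s, "not in covariate table"))
        for (s in setdiff(covs$subject, vs))
          note("sample-mismatch", paste("subject", s, "absent from VCF"))
      }
    }
  }
  if (length(diag)) do.call(rbind, diag) else
    data.frame(class = character(), message = character(),
               stringsAsFactors = FALSE)
}

#' Run the whole screening pipeline
#'
#' Either generates a synthetic cohort from \code{config$synth} (writing its
#' file bundle and re-ingesting it, so the file round trip is exercised) or
#' reads previously written input files, then builds the response phenotype,
#' screens every variant, fits final models for passing variants, and
#' estimates their power. All stage outputs are written to
#' \code{config$outdir} as tab-delimited tables plus a run log; given a seed
#' the bundle is byte-identical across runs.
#'
#' @param config list: \code{synth} (a \code{sim_config}) or \code{paths}
#'   (as in \code{\link{validate_inputs}}); \code{outdir}; optional
#'   \code{intensities} (default VIGOROUS and MODERATE), \code{outcomes},
#'   \code{alpha_bonf} (0.05), \code{alpha_by} (0.20), \code{power_nsims}
#'   (default 200), \code{power_alpha}, \code{final_covariates} (candidate
#'   covariate names), \code{log_covariates}.
#' @return invisibly, a list with all stage tables: \code{screening},
#'   \code{final}, \code{power}, \code{descriptives}, \code{log}.
#' @export
run_pipeline <- function(config) {
  outdir <- config$outdir %||% stop("config$outdir is required")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  intensities <- config$intensities %||% c("VIGOROUS", "MODERATE")
  outcomes <- config$outcomes %||% c("sbp", "dbp")
  alpha_bonf <- config$alpha_bonf %||% 0.05
  alpha_by <- config$alpha_by %||% 0.20
  logline <- character(0)
  say <- function(...) logline <<- c(logline, sprintf(...))

  if (!is.null(config$synth)) {
    cohort <- simulate_cohort(config$synth,
                              sessions = c("CONTROL", intensities))
    datadir <- file.path(outdir, "inputs")
    paths <- write_cohort(cohort, datadir,
                          nonpass_decoys = config$nonpass_decoys %||% 0L)
    say("synthetic cohort generated: %d subjects, %d variants, seed %d",
        nrow(cohort$subjects), nrow(cohort$config$variants),
        cohort$config$seed)
  } else {
    paths <- config$paths %||% stop("config needs either $synth or $paths")
  }
  diags <- validate_inputs(paths)
  if (nrow(diags)) {
    utils::write.table(diags, file.path(outdir, "diagnostics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stop("input validation failed; see diagnostics.tsv (first issue: ",
         diags$message[1L], ")")
  }
  covars <- utils::read.delim(paths$covariates, stringsAsFactors = FALSE)
  readings <- utils::read.delim(paths$readings, stringsAsFactors = FALSE)
  baseline <- utils::read.delim(paths$baseline, stringsAsFactors = FALSE)
  gm <- ingest_vcf(paths$vcf, samples = covars$subject)
  say("VCF ingested: %d PASS variant records, %d samples",
      ncol(gm$geno), length(gm$samples))

  groups <- split(covars$subject, covars$ethnicity)
  universes <- lapply(names(groups), function(e)
    tryCatch(build_profile_universe(gm, groups[[e]], e),
             error = function(err) NULL))
  names(universes) <- names(groups)
  for (e in names(universes))
    if (!is.null(universes[[e]]))
      say("unique genotype profiles (%s): K = %d", e, universes[[e]]$K)
  universes <- Filter(Negate(is.null), universes)
  groups <- groups[names(universes)]

  responses <- lapply(intensities, function(it)
    build_response_series(readings, baseline, it))
  names(responses) <- intensities
  for (it in intensities)
    say("%s responses: %d subjects (%d excluded by QC/completeness)", it,
        length(unique(responses[[it]]$subject)),
        length(attr(responses[[it]], "excluded")))

  screening <- run_screening(gm, responses, groups, universes,
                             outcomes = outcomes,
                             alpha_bonf = alpha_bonf, alpha_by = alpha_by)
  say("screening: %d tests, %d skipped (monomorphic), %d passing",
      nrow(screening), sum(screening$skipped), sum(screening$pass, na.rm = TRUE))

  passers <- screening[!screening$skipped & screening$pass, , drop = FALSE]
  final_rows <- list(); power_rows <- list()
  cand <- config$final_covariates %||% c("age", "bmi", "insulin",
                                         "triglycerides", "endothelin")
  logc <- config$log_covariates %||% c("insulin", "triglycerides", "endothelin")
  for (i in seq_len(nrow(passers))) {
    pr <- passers[i, ]
    subj <- groups[[pr$ethnicity]]
    resp <- responses[[pr$intensity]]
    resp <- resp[resp$subject %in% subj, , drop = FALSE]
    ma <- gm$geno[subj, pr$variant]; names(ma) <- subj
    elig <- select_covariates(resp, covars, cand, logc, outcome = pr$outcome)
    spec <- model_spec(outcome = pr$outcome, intensity = pr$intensity,
                       covariates = elig$covariate[elig$eligible],
                       log_covariates = intersect(logc,
                         elig$covariate[elig$eligible]),
                       interactions = TRUE)
    ff <- fit_final(spec, resp, covars, ma)
    final_rows[[length(final_rows) + 1L]] <- data.frame(
      variant = pr$variant, ethnicity = pr$ethnicity, outcome = pr$outcome,
      intensity = pr$intensity, r2_full = ff$r2_full,
      r2_nosnp = ff$r2_nosnp, partial_pve = ff$partial_pve,
      lrt_p = ff$lrt$p, overfit = ff$overfit_flag,
      formula = ff$formula, stringsAsFactors = FALSE)
    sv <- screen_variant(resp, ma, outcome = pr$outcome)
    pe <- power_from_fit(sv$fit_full, ar1_design(resp, ma, pr$outcome)$geno_cols,
                         n_sims = config$power_nsims %||% 200L,
                         alpha = config$power_alpha %||%
                           (alpha_bonf / universes[[pr$ethnicity]]$K),
                         seed = substream_seed(config$synth$seed %||% 1L, 500L + i))
    power_rows[[length(power_rows) + 1L]] <- data.frame(
      variant = pr$variant, ethnicity = pr$ethnicity, outcome = pr$outcome,
      intensity = pr$intensity, power = pe$power, se = pe$se,
      alpha = pe$alpha, n_sims = pe$n_sims, stringsAsFactors = FALSE)
  }
  final_tab <- if (length(final_rows)) do.call(rbind, final_rows) else
    data.frame(variant = character(), ethnicity = character(),
               outcome = character(), intensity = character(),
               r2_full = numeric(), r2_nosnp = numeric(),
               partial_pve = numeric(), lrt_p = numeric(),
               overfit = logical(), formula = character(),
               stringsAsFactors = FALSE)
  power_tab <- if (length(power_rows)) do.call(rbind, power_rows) else
    data.frame(variant = character(), ethnicity = character(),
               outcome = character(), intensity = character(),
               power = numeric(), se = numeric(), alpha = numeric(),
               n_sims = integer(), stringsAsFactors = FALSE)
  desc <- if (length(unique(covars$ethnicity)) == 2L)
    describe_cohort(covars, "ethnicity",
                    intersect(c("age", "bmi", "insulin", "triglycerides",
                                "endothelin"), names(covars))) else
    data.frame()
  wt <- function(x, f) utils::write.table(x, file.path(outdir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  wt(screening, "screening.tsv")
  wt(final_tab, "final_models.tsv")
  wt(power_tab, "power.tsv")
  wt(desc, "cohort_descriptives.tsv")
  writeLines(logline, file.path(outdir, "run_log.txt"))
  invisible(list(screening = screening, final = final_tab,
                 power = power_tab, descriptives = desc, log = logline))
}
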