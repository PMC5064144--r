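# Ambulatory BP phenotype construction: manufacturer-range QC, completeness,
# hourly aggregation, the exercise-minus-control response series, AASI, and
# genotype-group / cohort descriptive summaries.

#' Remove out-of-range ambulatory readings
#'
#' Applies the monitor manufacturer's exclusion criteria: a reading is removed
#' iff SBP > 220 or SBP < 80 mmHg, or DBP > 130 or DBP < 40 mmHg (strict
#' inequalities; boundary values are retained). Row order is preserved.
#'
#' @param readings data frame with numeric \code{sbp} and \code{dbp} columns.
#' @return the retained subset of rows.
#' @export
qc_readings <- function(readings) {
  stopifnot(all(c("sbp", "dbp") %in% names(readings)))
  if (nrow(readings) == 0L) return(readings)
  bad <- readings$sbp > 220 | readings$sbp < 80 |
         readings$dbp > 130 | readings$dbp < 40
  readings[!bad, , drop = FALSE]
}

#' Check the 80\% completeness rule for an ambulatory report
#'
#' @param retained number of readings retained after QC.
#' @param expected number of potential readings for the monitoring period.
#' @return \code{TRUE} iff \code{retained / expected >= 0.80}.
#' @export
completeness_ok <- function(retained, expected) {
  if (!is.finite(expected) || expected <= 0) stop("expected count must be > 0")
  retained / expected >= 0.80
}

#' Hourly means and change-from-baseline scores for one session
#'
#' Hour \code{h} covers timestamps in \code{[60(h-1), 60h)} minutes from
#' monitor attachment; all retained readings within an hour are weighted
#' equally. The change score subtracts the session's baseline mean (the
#' pre-session series averaged). Hours with no retained reading are returned
#' as missing.
#'
#' @param readings ambulatory readings for one subject-session (already
#'   QC'ed), with \code{timestamp_min}, \code{sbp}, \code{dbp}.
#' @param baseline pre-session baseline readings with \code{sbp}, \code{dbp}.
#' @param hours hour indices to aggregate over (default 1..19).
#' @return data frame: \code{hour}, \code{sbp}, \code{dbp} (hourly means),
#'   \code{sbp_change}, \code{dbp_change}.
#' @export
hourly_aggregate <- function(readings, baseline, hours = 1:19) {
  if (is.null(baseline) || nrow(baseline) == 0L)
    stop("unusable session: no baseline readings")
  h <- findInterval(readings$timestamp_min, 60 * (seq_len(max(hours)) - 1))
  agg <- function(v) {
    s <- tapply(v, factor(h, levels = hours), mean)
    as.numeric(s)
  }
  data.frame(hour = hours,
             sbp = agg(readings$sbp), dbp = agg(readings$dbp),
             sbp_change = agg(readings$sbp) - mean(baseline$sbp),
             dbp_change = agg(readings$dbp) - mean(baseline$dbp))
}

#' Hourly BP response of an exercise session relative to control
#'
#' The dependent variable of the whole analysis: per hour, (exercise change
#' from baseline) minus (control change from baseline), separately for SBP
#' and DBP. Defined only at hours where both sessions have a value.
#'
#' @param exercise,control data frames as returned by
#'   \code{\link{hourly_aggregate}} for the same subject.
#' @param subject optional subject id attached to the result.
#' @return data frame: \code{subject}, \code{hour}, \code{sbp}, \code{dbp}
#'   (response, mmHg; NA where either session is missing the hour).
#' @export
compute_response <- function(exercise, control, subject = NA_character_) {
  stopifnot(identical(exercise$hour, control$hour))
  data.frame(subject = subject, hour = exercise$hour,
             sbp = exercise$sbp_change - control$sbp_change,
             dbp = exercise$dbp_change - control$dbp_change,
             stringsAsFactors = FALSE)
}

#' Ambulatory arterial stiffness index
#'
#' AASI = 1 - (least-squares slope of DBP regressed on SBP) over the retained
#' control-session ambulatory readings.
#'
#' @param readings retained control readings with \code{sbp}, \code{dbp}.
#' @return dimensionless index.
#' @export
compute_aasi <- function(readings) {
  if (nrow(readings) < 3L) stop("AASI needs at least 3 retained readings")
  if (stats::var(readings$sbp) == 0) stop("AASI undefined: zero SBP variance")
  b <- stats::cov(readings$dbp, readings$sbp) / stats::var(readings$sbp)
  1 - b
}

#' Build the per-subject hourly response series for one exercise intensity
#'
#' End-to-end phenotype construction from raw tables: QC, completeness check,
#' hourly aggregation of the control and exercise sessions, and the
#' exercise-minus-control response. Subjects failing QC/completeness in
#' either session are dropped (recorded in the \code{"excluded"} attribute).
#'
#' @param readings long raw readings table (subject, session, timestamp_min,
#'   sbp, dbp, state).
#' @param baseline long baseline table (subject, session, timestamp_min,
#'   sbp, dbp).
#' @param intensity \code{"MODERATE"} or \code{"VIGOROUS"}.
#' @param hours monitored hours (default 1..19).
#' @param expected_readings potential readings per session used by the
#'   completeness rule; default 3 per waking hour 1-13 plus 2 per sleep hour
#'   14-19 (= 51 over 19 h).
#' @return long data frame (subject, hour, sbp, dbp) of responses.
#' @export
build_response_series <- function(readings, baseline, intensity,
                                  hours = 1:19,
                                  expected_readings = 3 * 13 + 2 * 6) {
  stopifnot(intensity %in% c("MODERATE", "VIGOROUS"))
  out <- list(); excluded <- character(0)
  for (sid in unique(readings$subject)) {
    per <- lapply(c("CONTROL", intensity), function(ses) {
      r <- qc_readings(readings[readings$subject == sid &
                                readings$session == ses, , drop = FALSE])
      b <- baseline[baseline$subject == sid & baseline$session == ses, ,
                    drop = FALSE]
      if (nrow(b) == 0L || !completeness_ok(nrow(r), expected_readings))
        return(NULL)
      hourly_aggregate(r, b, hours)
    })
    if (any(vapply(per, is.null, logical(1)))) {
      excluded <- c(excluded, sid)
      next
    }
    out[[sid]] <- compute_response(per[[2L]], per[[1L]], subject = sid)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(subject = character(), hour = integer(),
               sbp = numeric(), dbp = numeric())
  rownames(res) <- NULL
  attr(res, "excluded") <- excluded
  res
}

#' Genotype-group summaries of the 19-h averaged BP response
#'
#' For one variant: per number of minor alleles (0/1/2), the mean and SD of
#' the subject-level response averaged over non-missing hours, group sizes,
#' and the contrasts mean(1 MA) - mean(0 MA) and mean(2 MA) - mean(0 MA).
#' SD is reported as NA for groups of size 1.
#'
#' @param responses long response data frame (subject, hour, sbp, dbp).
#' @param ma named vector of minor-allele counts; names are subject ids and
#'   must cover every subject in \code{responses}.
#' @return list with \code{groups} (data frame: ma, n, sbp_mean, sbp_sd,
#'   dbp_mean, dbp_sd) and \code{contrasts} (data frame: ma, sbp, dbp).
#' @export
genotype_group_summary <- function(responses, ma) {
  subj <- unique(responses$subject)
  if (length(subj) == 0L) stop("no subjects in response set")
  if (!all(subj %in% names(ma)))
    stop("missing genotype for subject(s): ",
         paste(setdiff(subj, names(ma)), collapse = ", "))
  subj_mean <- function(col) {
    v <- tapply(responses[[col]], responses$subject, mean, na.rm = TRUE)
    v[subj]
  }
  sm <- subj_mean("sbp"); dm <- subj_mean("dbp")
  g <- ma[subj]
  groups <- do.call(rbind, lapply(0:2, function(k) {
    sel <- which(g == k)
    data.frame(ma = k, n = length(sel),
               sbp_mean = if (length(sel)) mean(sm[sel]) else NA_real_,
               sbp_sd = if (length(sel) > 1) stats::sd(sm[sel]) else NA_real_,
               dbp_mean = if (length(sel)) mean(dm[sel]) else NA_real_,
               dbp_sd = if (length(sel) > 1) stats::sd(dm[sel]) else NA_real_)
  }))
  base <- groups[groups$ma == 0L, ]
  contrasts <- do.call(rbind, lapply(1:2, function(k) {
    gk <- groups[groups$ma == k, ]
    data.frame(ma = k, sbp = gk$sbp_mean - base$sbp_mean,
               dbp = gk$dbp_mean - base$dbp_mean)
  }))
  list(groups = groups, contrasts = contrasts)
}

#' Cohort descriptive summary with between-group comparisons
#'
#' Mean and SD per group for each covariate, with an independent two-sample
#' t-test (Welch by default, pooled-variance optionally) between the two
#' groups.
#'
#' @param profiles subject table; one row per subject.
#' @param group name of the grouping column (two levels required).
#' @param covariates covariate column names; default all numeric columns.
#' @param pooled use the pooled-variance t-test instead of Welch.
#' @return data frame: covariate, per-group mean/sd, t, df, p. Covariates
#'   with zero variance in both groups get NA p and a flag.
#' @export
describe_cohort <- function(profiles, group = "ethnicity",
                            covariates = NULL, pooled = FALSE) {
  g <- factor(profiles[[group]])
  if (nlevels(g) != 2L) stop("exactly two groups are required")
  if (any(table(g) < 2L)) stop("at least 2 subjects per group are required")
  if (is.null(covariates))
    covariates <- names(profiles)[vapply(profiles, is.numeric, logical(1))]
  lv <- levels(g)
  do.call(rbind, lapply(covariates, function(cv) {
    x1 <- profiles[[cv]][g == lv[1L]]; x2 <- profiles[[cv]][g == lv[2L]]
    degenerate <- stats::sd(x1) == 0 && stats::sd(x2) == 0
    tt <- if (degenerate) NULL else
      stats::t.test(x1, x2, var.equal = pooled)
    data.frame(covariate = cv,
               mean_1 = mean(x1), sd_1 = stats::sd(x1),
               mean_2 = mean(x2), sd_2 = stats::sd(x2),
               t = if (degenerate) 0 else unname(tt$statistic),
               df = if (degenerate) NA_real_ else unname(tt$parameter),
               p = if (degenerate) NA_real_ else tt$p.value,
               degenerate = degenerate,
               stringsAsFactors = FALSE)
  }))
}
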