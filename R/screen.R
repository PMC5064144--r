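# Per-variant longitudinal screening: cubic time trend, additive genotype
# main effect and genotype-by-time interactions, AR1 within-subject errors,
# joint likelihood-ratio test, and profile-level Bonferroni/BY adjustment.

#' Assemble the stacked screening design for one variant
#'
#' Rows are (subject, hour) pairs with non-missing response. Time is centered
#' at hour 10 before forming powers to tame collinearity. The full design is
#' intercept, tc, tc^2, tc^3, \code{#MA}, and \code{#MA} x tc, tc^2, tc^3;
#' the reduced design drops all genotype terms.
#'
#' @param responses long response data frame (subject, hour, and the outcome
#'   column).
#' @param ma named minor-allele-count vector (subject -> 0/1/2); subjects
#'   with a missing genotype are excluded variant-wise.
#' @param outcome \code{"sbp"} or \code{"dbp"}.
#' @param time_center hour subtracted before forming polynomial terms.
#' @param interactions include genotype-by-time interaction columns.
#' @return list: \code{y}, \code{X_full}, \code{X_reduced}, \code{subject},
#'   \code{time}, \code{geno_cols} (indices of genotype terms in X_full).
#' @export
ar1_design <- function(responses, ma = NULL, outcome = "sbp",
                       time_center = 10, interactions = TRUE) {
  y <- responses[[outcome]]
  keep <- !is.na(y)
  if (!is.null(ma)) keep <- keep & !is.na(ma[responses$subject])
  d <- responses[keep, , drop = FALSE]
  y <- y[keep]
  tc <- d$hour - time_center
  Xr <- cbind(`(Intercept)` = 1, t = tc, t2 = tc^2, t3 = tc^3)
  if (is.null(ma))
    return(list(y = y, X_full = Xr, X_reduced = Xr, subject = d$subject,
                time = d$hour, geno_cols = integer(0)))
  g <- as.numeric(ma[d$subject])
  Xf <- cbind(Xr, snp = g)
  if (interactions)
    Xf <- cbind(Xf, snp_t = g * tc, snp_t2 = g * tc^2, snp_t3 = g * tc^3)
  list(y = y, X_full = Xf, X_reduced = Xr, subject = d$subject,
       time = d$hour, geno_cols = seq(ncol(Xr) + 1L, ncol(Xf)))
}

#' Screen one variant against the hourly BP response
#'
#' Fits the full (genotype main effect + genotype-by-time interactions) and
#' reduced (time-only) models by maximum likelihood under the requested
#' correlation structure and returns the joint likelihood-ratio p-value for
#' all genotype terms. Monomorphic variants are skipped.
#'
#' @param responses long response data frame for one ethnicity x intensity.
#' @param ma named minor-allele-count vector.
#' @param outcome \code{"sbp"} or \code{"dbp"}.
#' @param structure correlation structure (default AR1).
#' @param ref p-value reference: \code{"chisq"} (large-sample) or \code{"F"}
#'   (residual-degrees-of-freedom approximation).
#' @param interactions include genotype-by-time interactions in the test.
#' @return list: \code{p}, \code{statistic}, \code{df}, \code{fit_full},
#'   \code{fit_reduced}; or a list with \code{skipped = TRUE} and a
#'   \code{reason} for monomorphic variants.
#' @export
screen_variant <- function(responses, ma, outcome = "sbp", structure = "AR1",
                           ref = c("chisq", "F"), interactions = TRUE) {
  ref <- match.arg(ref)
  subj <- unique(responses$subject)
  g <- ma[subj]
  if (length(unique(g[!is.na(g)])) < 2L)
    return(list(skipped = TRUE, reason = "monomorphic", p = NA_real_))
  des <- ar1_design(responses, ma, outcome, interactions = interactions)
  full <- fit_ar1(des$y, des$X_full, des$subject, des$time,
                  method = "ML", structure = structure)
  red <- fit_ar1(des$y, des$X_reduced, des$subject, des$time,
                 method = "ML", structure = structure)
  lrt <- loglik_ratio_test(full, red)
  p <- if (ref == "chisq") lrt$p else
    residual_df_p(full, red, des$geno_cols)
  list(skipped = FALSE, p = p, statistic = lrt$statistic, df = lrt$df,
       fit_full = full, fit_reduced = red)
}

# F approximation with denominator df = n_obs - rank(full design), computed
# on the whitened scale at the full model's correlation parameter.
residual_df_p <- function(full, reduced_unused, geno_cols) {
  w <- whiten(cbind(full$y, full$X), full$subject, full$time,
              full$rho, full$structure)
  ys <- w$M[, 1L]; Xs <- w$M[, -1L, drop = FALSE]
  rss_f <- sum(.lm.fit(Xs, ys)$residuals^2)
  Xr <- Xs[, -geno_cols, drop = FALSE]
  rss_r <- sum(.lm.fit(Xr, ys)$residuals^2)
  q <- length(geno_cols)
  df2 <- full$n_obs - ncol(Xs)
  Fstat <- ((rss_r - rss_f) / q) / (rss_f / df2)
  stats::pf(Fstat, q, df2, lower.tail = FALSE)
}

#' Multiple-testing adjustment over the unique-profile universe
#'
#' Bonferroni: \code{min(1, p * K)}. Benjamini-Yekutieli: the step-up
#' adjustment \code{min(1, p_(i) * K * c(K) / i)} with the harmonic sum
#' \code{c(K) = sum(1/j, j = 1..K)}, made monotone non-increasing from the
#' largest rank, as implemented by \code{stats::p.adjust} with family size
#' \code{n = K}. K is the number of unique, variable genotype profiles in
#' the ethnic group, so the correction is applied at profile level.
#'
#' @param p raw p-values (one per tested profile, or per variant if already
#'   propagated).
#' @param K family size (must be >= \code{length(p)}).
#' @param method \code{"bonferroni"} or \code{"BY"}.
#' @return adjusted p-values in the input order.
#' @export
adjust_pvalues <- function(p, K, method = c("bonferroni", "BY")) {
  method <- match.arg(method)
  assert_prob(p, "p")
  if (K < length(p)) stop("K must be at least the number of tested profiles")
  if (method == "bonferroni") pmin(1, p * K)
  else stats::p.adjust(p, method = "BY", n = K)
}

#' Run the full per-variant screening
#'
#' One test per variant x ethnicity x outcome x intensity: the joint ML
#' likelihood-ratio test of all genotype terms under AR1, with Bonferroni and
#' BY adjustment over the ethnic group's unique-profile universe. Variants
#' sharing a genotype profile are fit once and share raw and adjusted
#' p-values; adjustment families are defined by ethnicity x intensity x
#' outcome. A variant passes if Bonferroni-adjusted p < \code{alpha_bonf} or
#' BY-adjusted p < \code{alpha_by}.
#'
#' @param gm a \code{genotype_matrix} (or bare matrix with rownames).
#' @param responses named list: \code{responses[[intensity]]} is the long
#'   response data frame for that intensity.
#' @param groups named list: ethnicity label -> subject ids.
#' @param universes optional named list of \code{profile_universe}s per
#'   ethnicity; built on the fly when absent.
#' @param outcomes outcome columns to screen.
#' @param alpha_bonf,alpha_by pass thresholds (0.05 and 0.20).
#' @param ref p-value reference passed to \code{\link{screen_variant}}.
#' @return data frame: variant, gene, ethnicity, outcome, intensity,
#'   \code{n_subjects}, \code{profile}, \code{raw_p}, \code{bonf_p},
#'   \code{by_p}, \code{K}, \code{pass}, \code{skipped}, group means by #MA.
#' @export
run_screening <- function(gm, responses, groups, universes = NULL,
                          outcomes = c("sbp", "dbp"),
                          alpha_bonf = 0.05, alpha_by = 0.20,
                          ref = "chisq") {
  M <- if (inherits(gm, "genotype_matrix")) gm$geno else as.matrix(gm)
  meta <- if (inherits(gm, "genotype_matrix")) gm$variants else
    data.frame(name = colnames(M), gene = NA_character_,
               chrom = NA_character_, pos = seq_len(ncol(M)),
               stringsAsFactors = FALSE)
  ord <- order(meta$gene, meta$chrom, meta$pos)
  res <- list()
  for (eth in names(groups)) {
    subj <- intersect(groups[[eth]], rownames(M))
    uni <- if (!is.null(universes)) universes[[eth]] else
      tryCatch(build_profile_universe(M, subj, eth), error = function(e) NULL)
    if (is.null(uni)) stop("no profile universe available for group ", eth)
    for (intensity in names(responses)) {
      resp_all <- responses[[intensity]]
      resp <- resp_all[resp_all$subject %in% subj, , drop = FALSE]
      for (outc in outcomes) {
        fam <- list()       # profile id -> p (fit once per unique profile)
        rows <- list()
        for (j in ord) {
          vn <- meta$name[j] %||% colnames(M)[j]
          prof <- uni$profile[colnames(M)[j]]
          ma <- M[subj, j]; names(ma) <- subj
          if (is.na(prof)) {
            rows[[vn]] <- data.frame(
              variant = vn, gene = meta$gene[j], ethnicity = eth,
              outcome = outc, intensity = intensity,
              n_subjects = length(subj), profile = NA_integer_,
              raw_p = NA_real_, K = uni$K, skipped = TRUE,
              stringsAsFactors = FALSE)
            next
          }
          key <- as.character(prof)
          if (is.null(fam[[key]])) {
            sv <- screen_variant(resp, ma, outcome = outc, ref = ref)
            fam[[key]] <- sv$p
          }
          rows[[vn]] <- data.frame(
            variant = vn, gene = meta$gene[j], ethnicity = eth,
            outcome = outc, intensity = intensity,
            n_subjects = length(subj), profile = unname(prof),
            raw_p = fam[[key]], K = uni$K, skipped = FALSE,
            stringsAsFactors = FALSE)
        }
        tab <- do.call(rbind, rows)
        # adjust once per unique profile, then propagate to shared variants
        pid <- unique(tab$profile[!tab$skipped])
        praw <- vapply(pid, function(id)
          tab$raw_p[!tab$skipped & tab$profile == id][1L], numeric(1))
        bonf <- adjust_pvalues(praw, uni$K, "bonferroni")
        by <- adjust_pvalues(praw, uni$K, "BY")
        tab$bonf_p <- bonf[match(tab$profile, pid)]
        tab$by_p <- by[match(tab$profile, pid)]
        tab$pass <- !tab$skipped &
          (tab$bonf_p < alpha_bonf | tab$by_p < alpha_by)
        res[[length(res) + 1L]] <- tab
      }
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
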