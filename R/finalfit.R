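# Final multivariable models for variants passing the screen: marginal
# covariate eligibility, structure/coding selection by AIC and LRT, REML
# coefficient estimates, Magee pseudo-R2 and partial proportion of variance
# explained.

#' Specify a final multivariable model
#'
#' @param outcome \code{"sbp"} or \code{"dbp"}.
#' @param intensity exercise intensity the response series comes from.
#' @param covariates subject-level covariate names to include.
#' @param log_covariates subset of \code{covariates} entered as natural logs.
#' @param poly_order polynomial order of the time trend, 0..3.
#' @param coding genetic coding: \code{"additive"} (#MA), \code{"dominant"}
#'   (1 if #MA >= 1) or \code{"recessive"} (1 if #MA = 2).
#' @param structure within-subject correlation structure.
#' @param interactions include genotype-by-time interaction terms.
#' @param center center covariates at the modeled subgroup mean (the genotype
#'   term is never centered).
#' @return list of class \code{model_spec}.
#' @export
model_spec <- function(outcome = "sbp", intensity = "VIGOROUS",
                       covariates = character(0),
                       log_covariates = character(0),
                       poly_order = 3L,
                       coding = c("additive", "dominant", "recessive"),
                       structure = c("AR1", "CS", "independent"),
                       interactions = FALSE, center = TRUE) {
  coding <- match.arg(coding)
  structure <- match.arg(structure)
  stopifnot(poly_order %in% 0:3, all(log_covariates %in% covariates))
  structure(list(outcome = outcome, intensity = intensity,
                 covariates = covariates, log_covariates = log_covariates,
                 poly_order = as.integer(poly_order), coding = coding,
                 structure = structure, interactions = interactions,
                 center = center), class = "model_spec")
}

code_genotype <- function(ma, coding) {
  switch(coding,
         additive = as.numeric(ma),
         dominant = as.numeric(ma >= 1),
         recessive = as.numeric(ma == 2))
}

# Stacked design for a model_spec. `covars` is the subject table; `ma` a
# named #MA vector or NULL for a no-genotype model.
final_design <- function(spec, responses, covars, ma = NULL,
                         time_center = 10) {
  y <- responses[[spec$outcome]]
  keep <- !is.na(y)
  if (!is.null(ma)) keep <- keep & !is.na(ma[responses$subject])
  d <- responses[keep, , drop = FALSE]
  y <- y[keep]
  tc <- d$hour - time_center
  X <- matrix(1, length(y), 1L, dimnames = list(NULL, "(Intercept)"))
  if (spec$poly_order >= 1L)
    for (k in seq_len(spec$poly_order)) {
      X <- cbind(X, tc^k)
      colnames(X)[ncol(X)] <- paste0("time", if (k > 1) k else "")
    }
  for (cv in spec$covariates) {
    v <- covars[[cv]][match(d$subject, covars$subject)]
    nm <- cv
    if (cv %in% spec$log_covariates) { v <- log(v); nm <- paste0("log(", cv, ")") }
    if (spec$center) v <- v - mean(v[!duplicated(d$subject)])
    X <- cbind(X, v); colnames(X)[ncol(X)] <- nm
  }
  geno_cols <- integer(0)
  if (!is.null(ma)) {
    g <- code_genotype(ma[d$subject], spec$coding)
    X <- cbind(X, snp = g)
    geno_cols <- ncol(X)
    if (spec$interactions && spec$poly_order >= 1L) {
      for (k in seq_len(spec$poly_order)) {
        X <- cbind(X, g * tc^k)
        colnames(X)[ncol(X)] <- paste0("snp_time", if (k > 1) k else "")
        geno_cols <- c(geno_cols, ncol(X))
      }
    }
  }
  list(y = y, X = X, subject = d$subject, time = d$hour,
       geno_cols = geno_cols)
}

#' Marginal covariate eligibility for the final models
#'
#' A candidate covariate is eligible iff its single-covariate model
#' (intercept + covariate, AR1 errors, ML) improves on the intercept-only
#' model at LRT p < 0.05. Log transforms are applied before testing when
#' flagged; constant covariates are ineligible.
#'
#' @param responses long response data frame.
#' @param covars subject covariate table (must contain \code{subject}).
#' @param candidates covariate names to test.
#' @param log_candidates subset tested on the natural-log scale.
#' @param outcome response column.
#' @param structure correlation structure (default AR1).
#' @param alpha eligibility threshold (default 0.05).
#' @return data frame: covariate, p, eligible, reason.
#' @export
select_covariates <- function(responses, covars, candidates,
                              log_candidates = character(0),
                              outcome = "sbp", structure = "AR1",
                              alpha = 0.05) {
  do.call(rbind, lapply(candidates, function(cv) {
    v <- covars[[cv]][match(responses$subject, covars$subject)]
    if (cv %in% log_candidates) v <- log(v)
    if (length(unique(v[!is.na(v)])) < 2L)
      return(data.frame(covariate = cv, p = NA_real_, eligible = FALSE,
                        reason = "constant", stringsAsFactors = FALSE))
    keep <- !is.na(responses[[outcome]]) & !is.na(v)
    y <- responses[[outcome]][keep]
    X1 <- cbind(`(Intercept)` = 1, cov = v[keep])
    X0 <- X1[, 1L, drop = FALSE]
    f1 <- fit_ar1(y, X1, responses$subject[keep], responses$hour[keep],
                  method = "ML", structure = structure)
    f0 <- fit_ar1(y, X0, responses$subject[keep], responses$hour[keep],
                  method = "ML", structure = structure)
    p <- loglik_ratio_test(f1, f0)$p
    data.frame(covariate = cv, p = p, eligible = p < alpha, reason = "",
               stringsAsFactors = FALSE)
  }))
}

#' Select the best model specification by AIC
#'
#' All candidates are fit by ML on identical rows; the minimum-AIC candidate
#' wins, with \code{AIC = -2 logLik + 2 (p_fixed + p_correlation + 1)}. Ties
#' go to the model with fewer parameters, then to the structure order
#' AR1 > CS > independent. Candidates that fail to converge are excluded
#' with a warning.
#'
#' @param specs list of \code{model_spec}s.
#' @param responses,covars,ma data as for \code{\link{fit_final}}.
#' @return list: \code{best} (a \code{model_spec}), \code{table} (AIC per
#'   candidate).
#' @export
select_model <- function(specs, responses, covars, ma = NULL) {
  if (inherits(specs, "model_spec")) specs <- list(specs)
  rows <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    fit <- tryCatch({
      des <- final_design(sp, responses, covars, ma)
      fit_ar1(des$y, des$X, des$subject, des$time,
              method = "ML", structure = sp$structure)
    }, error = function(e) {
      warning("candidate ", i, " excluded: ", conditionMessage(e))
      NULL
    })
    if (is.null(fit)) return(NULL)
    k <- fit$rank + 1 + (sp$structure != "independent")
    data.frame(candidate = i, structure = sp$structure, coding = sp$coding,
               poly_order = sp$poly_order, n_params = k,
               logLik = fit$logLik, AIC = aic_ar1(fit),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || !nrow(tab)) stop("no candidate model converged")
  sorder <- c(AR1 = 1L, CS = 2L, independent = 3L)
  o <- order(round(tab$AIC, 10), tab$n_params, sorder[tab$structure])
  list(best = specs[[tab$candidate[o[1L]]]], table = tab)
}

#' Magee likelihood-ratio pseudo-R-squared
#'
#' \eqn{R^2_m = 1 - (L_R / L_U)^{2/n}}, computed in log space as
#' \code{1 - exp((2/n) * (llR - llU))}, where \code{llR} is the maximized
#' log-likelihood of the intercept-only reference model, \code{llU} that of
#' the model of interest, and \code{n} the number of subjects.
#'
#' @param llU,llR log-likelihoods (unrestricted and intercept-only).
#' @param n number of subjects.
#' @return pseudo-R-squared in [0, 1).
#' @export
magee_r2 <- function(llU, llR, n) {
  stopifnot(n >= 1)
  if (llR > llU + 1e-8)
    stop("reference model has higher likelihood than the full model")
  1 - exp((2 / n) * (llR - llU))
}

#' Fit a final multivariable model and its variance-explained summary
#'
#' Coefficients are reported from a REML fit; model comparison quantities
#' (Magee pseudo-R2, partial PVE, the genotype LRT) come from ML fits of the
#' full model, the model with all genotype terms removed, and an
#' intercept-only reference retaining the selected correlation structure.
#' Partial PVE = R2_m(full) - R2_m(no genotype). When a genotype group has
#' one subject or fewer the fit proceeds but is flagged as a potential
#' overfit.
#'
#' @param spec a \code{model_spec}.
#' @param responses long response data frame (subject, hour, outcome).
#' @param covars subject covariate table.
#' @param ma named minor-allele-count vector.
#' @return list of class \code{final_fit}: \code{spec}, \code{coef} (REML
#'   table), \code{rho}, \code{sigma2}, \code{r2_full}, \code{r2_nosnp},
#'   \code{partial_pve}, \code{lrt} (statistic, df, p), \code{formula}
#'   (Table-style rendering), \code{overfit_flag}, \code{logLik} pieces.
#' @export
fit_final <- function(spec, responses, covars, ma) {
  des <- final_design(spec, responses, covars, ma)
  reml <- fit_ar1(des$y, des$X, des$subject, des$time,
                  method = "REML", structure = spec$structure)
  full <- fit_ar1(des$y, des$X, des$subject, des$time,
                  method = "ML", structure = spec$structure)
  Xn <- des$X[, -des$geno_cols, drop = FALSE]
  nosnp <- fit_ar1(des$y, Xn, des$subject, des$time,
                   method = "ML", structure = spec$structure)
  int <- fit_ar1(des$y, des$X[, 1L, drop = FALSE], des$subject, des$time,
                 method = "ML", structure = spec$structure)
  n_sub <- full$n_subjects
  r2_full <- magee_r2(full$logLik, int$logLik, n_sub)
  r2_nosnp <- magee_r2(nosnp$logLik, int$logLik, n_sub)
  lrt <- loglik_ratio_test(full, nosnp)
  g <- code_genotype(ma[unique(des$subject)], spec$coding)
  overfit <- any(table(factor(g, levels = sort(unique(g)))) <= 1L)
  structure(list(
    spec = spec, coef = cbind(Estimate = reml$coefficients, SE = reml$se),
    rho = reml$rho, sigma2 = reml$sigma2,
    r2_full = r2_full, r2_nosnp = r2_nosnp,
    partial_pve = r2_full - r2_nosnp, lrt = lrt,
    logLik_full = full$logLik, logLik_nosnp = nosnp$logLik,
    logLik_intercept = int$logLik,
    formula = render_formula(reml$coefficients, spec),
    overfit_flag = overfit, n_subjects = n_sub, n_obs = full$n_obs),
    class = "final_fit")
}

# Human-readable model rendering patterned on a published coefficient table;
# covariates are centered (noted), the genotype term is not.
render_formula <- function(beta, spec) {
  term <- names(beta)
  term[term == "(Intercept)"] <- ""
  lab <- ifelse(term == "", sprintf("%.4f", beta),
                sprintf("%+.4f*%s", beta, term))
  snp_lab <- if (spec$coding == "recessive") "SNPr" else "SNP"
  lab <- gsub("snp_time", paste0(snp_lab, "*time"), lab, fixed = TRUE)
  lab <- gsub("\\bsnp\\b", snp_lab, lab)
  paste0("BP response = ", paste(lab, collapse = " "),
         " [covariates centered except the polymorphism; ",
         spec$structure, " errors]")
}

#' @export
print.final_fit <- function(x, ...) {
  cat(x$formula, "\n")
  cat(sprintf("R2_m (full) = %.4f; R2_m (no SNP) = %.4f; partial PVE = %.4f\n",
              x$r2_full, x$r2_nosnp, x$partial_pve))
  cat(sprintf("genotype LRT: chi2 = %.3f, df = %d, p = %.3g%s\n",
              x$lrt$statistic, x$lrt$df, x$lrt$p,
              if (x$overfit_flag) "  [potential overfit: group n <= 1]" else ""))
  invisible(x)
}
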