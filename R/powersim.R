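# Parametric simulation of the screening method's power: data are simulated
# from the fitted screening model (fixed genotypes, AR1 noise), refit, and
# the genotype terms tested with the residual-degrees-of-freedom F method.

#' Estimate the power of the variant screening by simulation
#'
#' Each replicate simulates the stacked hourly responses from the generative
#' model \eqn{y = X\beta + e}, with \eqn{e} AR1(\eqn{\rho}, \eqn{\sigma^2})
#' within subject, refits full and reduced models, and computes the joint
#' genotype-term p-value with an F reference whose denominator degrees of
#' freedom are \code{n_obs - rank(X_full)}. Power is the proportion of
#' replicates with p below \code{alpha}.
#'
#' In the default fast mode the correlation parameter is held at the
#' generative \eqn{\rho} during refitting (the whitened designs are then
#' fixed across replicates and the simulation is vectorized); with
#' \code{refit_rho = TRUE} each replicate re-estimates \eqn{\rho} by profiled
#' ML, propagating its estimation noise into the power estimate.
#'
#' @param X full design matrix (including all genotype terms).
#' @param subject,time stacking structure, as in \code{\link{fit_ar1}}.
#' @param beta generative coefficient vector (length \code{ncol(X)}).
#' @param sigma2,rho generative residual variance and autocorrelation.
#' @param geno_cols indices of the genotype columns of \code{X} being tested.
#' @param n_sims number of replicates (default 1000).
#' @param alpha significance threshold; default the Bonferroni level
#'   0.05/300 over the African-American profile universe.
#' @param seed integer seed; the estimate is deterministic given it.
#' @param refit_rho re-estimate the correlation per replicate.
#' @return list of class \code{power_estimate}: \code{power}, \code{se}
#'   (binomial Monte-Carlo SE), \code{n_sims}, \code{alpha}.
#' @export
estimate_power <- function(X, subject, time, beta, sigma2, rho, geno_cols,
                           n_sims = 1000L, alpha = 0.05 / 300, seed = 1L,
                           refit_rho = FALSE) {
  stopifnot(alpha > 0, alpha < 1, n_sims >= 1)
  X <- as.matrix(X)
  stopifnot(length(beta) == ncol(X), length(geno_cols) >= 1)
  ord <- order(match(subject, unique(subject)), time)
  X <- X[ord, , drop = FALSE]
  subject <- subject[ord]; time <- as.numeric(time)[ord]
  n <- nrow(X)
  mu <- as.vector(X %*% beta)
  q <- length(geno_cols)
  p_full <- qr(X)$rank
  df2 <- n - p_full
  sigma <- sqrt(sigma2)

  # AR1 innovation representation over the stacked vector
  first <- !duplicated(subject)
  idx <- which(!first)
  a <- rho^(time[idx] - time[idx - 1L])
  innov_sd <- rep(sigma, n)
  innov_sd[idx] <- sigma * sqrt(1 - a^2)

  a_full <- numeric(n); a_full[idx] <- a
  simulate_errors <- function(m) {
    E <- matrix(stats::rnorm(n * m, 0, innov_sd), n, m)
    for (j in idx) E[j, ] <- E[j, ] + a_full[j] * E[j - 1L, ]
    E
  }

  set.seed(substream_seed(seed, 11L))
  if (!refit_rho) {
    w <- whiten(X, subject, time, rho, "AR1")
    Xs <- w$M
    Qf <- qr.Q(qr(Xs))
    Qr <- qr.Q(qr(Xs[, -geno_cols, drop = FALSE]))
    block <- 250L
    hits <- 0L
    done <- 0L
    while (done < n_sims) {
      m <- min(block, n_sims - done)
      E <- simulate_errors(m)
      Y <- mu + E
      Ys <- whiten(Y, subject, time, rho, "AR1")$M
      tot <- colSums(Ys^2)
      rss_f <- tot - colSums(crossprod(Qf, Ys)^2)
      rss_r <- tot - colSums(crossprod(Qr, Ys)^2)
      Fstat <- ((rss_r - rss_f) / q) / (rss_f / df2)
      p <- stats::pf(Fstat, q, df2, lower.tail = FALSE)
      hits <- hits + sum(p < alpha)
      done <- done + m
    }
  } else {
    hits <- 0L
    for (s in seq_len(n_sims)) {
      y <- mu + as.vector(simulate_errors(1L))
      fit <- fit_ar1(y, X, subject, time, method = "ML", structure = "AR1")
      p <- residual_df_p(fit, NULL, geno_cols)
      if (p < alpha) hits <- hits + 1L
    }
  }
  pw <- hits / n_sims
  structure(list(power = pw, se = sqrt(pw * (1 - pw) / n_sims),
                 n_sims = as.integer(n_sims), alpha = alpha),
            class = "power_estimate")
}

#' Power estimate from a fitted screening model
#'
#' Convenience wrapper: takes the full-model \code{ar1_fit} from
#' \code{\link{screen_variant}} and simulates from its estimated
#' \eqn{\hat\beta}, \eqn{\hat\sigma^2}, \eqn{\hat\rho} with the observed
#' genotypes held fixed.
#'
#' @param fit the full-model \code{ar1_fit}.
#' @param geno_cols genotype column indices in the fit's design.
#' @param ... passed to \code{\link{estimate_power}}.
#' @return a \code{power_estimate}.
#' @export
power_from_fit <- function(fit, geno_cols, ...) {
  estimate_power(fit$X, fit$subject, fit$time, fit$coefficients,
                 fit$sigma2, fit$rho, geno_cols, ...)
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("power = %.3f (MC SE %.3f) at alpha = %.3g over %d simulations\n",
              x$power, x$se, x$alpha, x$n_sims))
  invisible(x)
}
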