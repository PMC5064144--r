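# Exact whitening of one stacked (y, X) system under a block-diagonal
# within-subject correlation structure. Rows must already be ordered by
# (subject, time). Returns the transformed matrix plus log|R| summed over
# subject blocks, so that for V = sigma^2 R,
#   -2 logLik = N log(2 pi sigma^2) + log|R| + RSS_whitened / sigma^2.
#
# AR1 uses the innovations (Cholesky) form: within a subject, with gap
# d_j = t_j - t_{j-1}, a_j = rho^{d_j},
#   w_1 = x_1,  w_j = (x_j - a_j x_{j-1}) / sqrt(1 - a_j^2),
# which is exact for the continuous-lag correlation rho^{|dt|} and coincides
# with classical AR1 at unit spacing. Compound symmetry (CS) whitens via the
# closed-form eigenstructure of (1-rho) I + rho J.
whiten <- function(M, subject, time, rho, structure) {
  M <- as.matrix(M)
  n <- nrow(M)
  if (structure == "independent" || rho == 0 && structure == "AR1")
    return(list(M = M, logdet = 0))
  if (structure == "AR1") {
    first <- !duplicated(subject)
    idx <- which(!first)
    d <- time[idx] - time[idx - 1L]
    if (any(d <= 0)) stop("times must be strictly increasing within subject")
    a <- rho^d
    s2 <- 1 - a * a
    if (any(s2 <= 0)) stop("degenerate AR1 correlation (|rho| too close to 1)")
    s <- sqrt(s2)
    W <- M
    W[idx, ] <- (M[idx, , drop = FALSE] - a * M[idx - 1L, , drop = FALSE]) / s
    list(M = W, logdet = sum(log(s2)))
  } else if (structure == "CS") {
    f <- factor(subject, levels = unique(subject))
    m <- as.vector(table(f))[as.integer(f)]       # block size per row
    mb <- as.vector(table(f))                     # per block
    if (rho <= max(-1 / (max(mb) - 1), -1) || rho >= 1)
      stop("CS correlation parameter out of admissible range")
    gm <- rowsum(M, f, reorder = FALSE) / mb      # block means
    theta <- 1 - sqrt((1 - rho) / (1 + (m - 1) * rho))
    W <- (M - theta * gm[as.integer(f), , drop = FALSE]) / sqrt(1 - rho)
    list(M = W, logdet = sum((mb - 1) * log(1 - rho) + log(1 + (mb - 1) * rho)))
  } else stop("unknown correlation structure: ", structure)
}

# Profiled -2 * objective pieces at a fixed correlation parameter: whitened
# regression by QR, closed-form sigma^2, and the (restricted) log-likelihood.
ar1_profile <- function(rho, y, X, subject, time, structure, method) {
  n <- length(y)
  p <- ncol(X)
  w <- whiten(cbind(y, X), subject, time, rho, structure)
  ys <- w$M[, 1L]
  Xs <- w$M[, -1L, drop = FALSE]
  fit <- .lm.fit(Xs, ys)
  rss <- sum(fit$residuals^2)
  if (method == "ML") {
    sigma2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi * sigma2) + w$logdet + n)
  } else {
    sigma2 <- rss / (n - p)
    ldXX <- 2 * sum(log(abs(diag(qr.R(qr(Xs))))))
    ll <- -0.5 * ((n - p) * log(2 * pi * sigma2) + w$logdet + ldXX + (n - p))
  }
  list(ll = ll, sigma2 = sigma2, rss = rss, ys = ys, Xs = Xs, logdet = w$logdet)
}

#' Fit a linear model with within-subject serial correlation
#'
#' Fits \eqn{y = X\beta + e} where residuals are independent across subjects
#' and, within a subject, follow a first-order autoregressive (AR1), compound
#' symmetry (CS), or independence correlation structure with common residual
#' variance \eqn{\sigma^2}. For a fixed correlation parameter \eqn{\rho} the
#' coefficients and \eqn{\sigma^2} have closed forms after exact whitening of
#' each subject's block; \eqn{\rho} maximizes the profiled (restricted)
#' log-likelihood by bounded one-dimensional search. Missing hours are handled
#' through the continuous-lag correlation \eqn{\rho^{|\Delta t|}}.
#'
#' @param y numeric response vector (stacked hourly values, mmHg).
#' @param X design matrix; an intercept column must be included explicitly.
#' @param subject subject identifier per row; rows are regrouped by subject.
#' @param time numeric time (hour) per row, increasing within subject.
#' @param method \code{"ML"} (for likelihood-ratio tests, AIC, pseudo-R2) or
#'   \code{"REML"} (for reported coefficient estimates).
#' @param structure \code{"AR1"}, \code{"CS"} or \code{"independent"}.
#' @param rho optional fixed correlation parameter; when supplied no search is
#'   performed (use 0 with \code{structure = "AR1"} to reproduce OLS).
#' @param interval search bounds for the correlation parameter.
#' @param tol convergence tolerance on the profiled log-likelihood search.
#' @return an object of class \code{ar1_fit}: coefficients with standard
#'   errors, \code{sigma2}, \code{rho}, \code{logLik}, the fit method and
#'   structure, ranks and dimensions, and the (reordered) model frame pieces.
#' @examples
#' d <- expand.grid(hour = 1:6, id = 1:8)
#' X <- cbind(1, d$hour)
#' y <- X %*% c(2, 0.5) + rnorm(nrow(d))
#' fit_ar1(y, X, d$id, d$hour)
#' @export
fit_ar1 <- function(y, X, subject, time,
                    method = c("ML", "REML"),
                    structure = c("AR1", "CS", "independent"),
                    rho = NULL, interval = c(-0.99, 0.99), tol = 1e-8) {
  method <- match.arg(method)
  structure <- match.arg(structure)
  y <- as.numeric(y)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  keep <- stats::complete.cases(y, X, subject, time)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  subject <- subject[keep]; time <- as.numeric(time)[keep]
  ord <- order(match(subject, unique(subject)), time)
  y <- y[ord]; X <- X[ord, , drop = FALSE]
  subject <- subject[ord]; time <- time[ord]
  n <- length(y)
  n_sub <- length(unique(subject))
  if (n_sub < 2L) stop("at least 2 subjects are required")

  # drop aliased columns once, on the raw design (aliasing is rho-invariant)
  q0 <- qr(X)
  if (q0$rank < ncol(X)) {
    drop <- q0$pivot[-seq_len(q0$rank)]
    warning("dropping aliased design column(s): ",
            paste(colnames(X)[drop], collapse = ", "))
    X <- X[, -drop, drop = FALSE]
  }
  p <- ncol(X)

  if (structure == "independent") {
    rho_hat <- 0
  } else if (!is.null(rho)) {
    rho_hat <- rho
  } else {
    lo <- interval[1L]
    if (structure == "CS") {
      mmax <- max(table(subject))
      lo <- max(lo, -1 / (mmax - 1) + 1e-6)
    }
    opt <- stats::optimize(function(r)
      ar1_profile(r, y, X, subject, time, structure, method)$ll,
      lower = lo, upper = interval[2L], maximum = TRUE, tol = tol)
    rho_hat <- opt$maximum
    # guard against a boundary maximum the interior search can miss
    for (r_end in c(lo, interval[2L])) {
      if (ar1_profile(r_end, y, X, subject, time, structure, method)$ll >
          opt$objective + 1e-10) rho_hat <- r_end
    }
  }

  pr <- ar1_profile(rho_hat, y, X, subject, time, structure, method)
  qrXs <- qr(pr$Xs)
  beta <- qr.coef(qrXs, pr$ys)
  XtXinv <- chol2inv(qr.R(qrXs))
  se <- sqrt(pr$sigma2 * diag(XtXinv))
  names(beta) <- names(se) <- colnames(X)
  structure(list(
    coefficients = beta, se = se, sigma2 = pr$sigma2, rho = rho_hat,
    logLik = pr$ll, method = method, structure = structure,
    n_obs = n, n_subjects = n_sub, rank = p, rss_whitened = pr$rss,
    logdet = pr$logdet, y = y, X = X, subject = subject, time = time,
    vcov = pr$sigma2 * XtXinv), class = "ar1_fit")
}

#' @export
print.ar1_fit <- function(x, ...) {
  cat(sprintf("Linear model with %s within-subject errors (%s)\n",
              x$structure, x$method))
  cat(sprintf("  %d obs, %d subjects; sigma^2 = %.4g, rho = %.4f, logLik = %.4f\n",
              x$n_obs, x$n_subjects, x$sigma2, x$rho, x$logLik))
  print(cbind(Estimate = x$coefficients, `Std.Error` = x$se))
  invisible(x)
}

#' @export
logLik.ar1_fit <- function(object, ...) {
  structure(object$logLik, df = object$rank + (object$structure != "independent") + 1,
            class = "logLik")
}

#' @export
coef.ar1_fit <- function(object, ...) object$coefficients

#' Akaike information criterion for a serial-correlation fit
#'
#' \code{AIC = -2 logLik + 2 k} with \code{k} counting the fixed effects, the
#' residual variance, and the correlation parameter (when the structure has
#' one).
#' @param fit an \code{ar1_fit}.
#' @return numeric AIC.
#' @export
aic_ar1 <- function(fit) {
  k <- fit$rank + 1 + (fit$structure != "independent")
  -2 * fit$logLik + 2 * k
}

#' Likelihood-ratio test of two nested ML fits
#'
#' @param full,reduced \code{ar1_fit} objects fit by maximum likelihood on the
#'   identical rows, with the reduced fixed-effect design nested in the full.
#' @return list with \code{statistic}, \code{df} (difference in fixed-effect
#'   rank) and \code{p} from the chi-square upper tail.
#' @export
loglik_ratio_test <- function(full, reduced) {
  if (full$method != "ML" || reduced$method != "ML")
    stop("likelihood-ratio tests require ML fits; REML likelihoods with ",
         "different fixed effects are not comparable")
  if (full$n_obs != reduced$n_obs)
    stop("fits must use identical observations")
  stat <- 2 * (full$logLik - reduced$logLik)
  if (stat < -1e-6) stop("full model has lower likelihood; models not nested?")
  stat <- max(stat, 0)
  df <- full$rank - reduced$rank
  if (df < 0) stop("reduced model is larger than the full model")
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}
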