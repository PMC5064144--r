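# Independent oracles and small generators shared across the suite.

# Dense brute-force generalized least squares: explicit block covariance,
# solve() and log-determinant, no whitening. The reference implementation
# the fast fitter must agree with.
dense_gls <- function(y, X, subject, time, rho, structure, method = "ML") {
  ord <- order(match(subject, unique(subject)), time)
  y <- y[ord]; X <- X[ord, , drop = FALSE]
  subject <- subject[ord]; time <- time[ord]
  blocks <- lapply(unique(subject), function(s) {
    tt <- time[subject == s]
    if (structure == "AR1") outer(tt, tt, function(a, b) rho^abs(a - b))
    else if (structure == "CS") {
      m <- length(tt); M <- matrix(rho, m, m); diag(M) <- 1; M
    } else diag(length(tt))
  })
  R <- as.matrix(Matrix::bdiag(blocks))
  Ri <- solve(R)
  b <- solve(t(X) %*% Ri %*% X, t(X) %*% Ri %*% y)
  r <- y - X %*% b
  n <- length(y); p <- ncol(X)
  rss <- as.numeric(t(r) %*% Ri %*% r)
  ld <- as.numeric(determinant(R, logarithm = TRUE)$modulus)
  if (method == "ML") {
    s2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi * s2) + ld + n)
  } else {
    s2 <- rss / (n - p)
    ldx <- as.numeric(determinant(t(X) %*% Ri %*% X, logarithm = TRUE)$modulus)
    ll <- -0.5 * ((n - p) * log(2 * pi * s2) + ld + ldx + (n - p))
  }
  list(beta = as.vector(b), ll = ll, sigma2 = s2)
}

# Direct transcription of the Benjamini-Yekutieli step-up adjustment over a
# family of size K: p_(i) * K * c(K) / i, monotone from the largest rank.
brute_force_by <- function(p, K) {
  cK <- sum(1 / seq_len(K))
  o <- order(p)
  i <- seq_along(p)
  adj <- pmin(1, p[o] * K * cK / i)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(length(p))
  out[o] <- adj
  out
}

# Stationary AR1 Gaussian series, used to build model-true response data.
ar1_series <- function(m, rho, sigma) {
  v <- numeric(m)
  v[1] <- rnorm(1, 0, sigma)
  if (m > 1) for (t in 2:m)
    v[t] <- rho * v[t - 1] + rnorm(1, 0, sigma * sqrt(1 - rho^2))
  v
}

# Long response frame generated straight from the screening model:
# y = Xb (cubic time + additive genotype terms) + AR1 noise.
make_model_responses <- function(n_sub, m = 19, rho = 0.5, sigma = 6,
                                 ma = NULL, beta_snp = 0,
                                 delta = c(0, 0, 0), trend = c(0, 0, 0, 0)) {
  sub <- sprintf("S%03d", seq_len(n_sub))
  d <- data.frame(subject = rep(sub, each = m), hour = rep(seq_len(m), n_sub))
  tc <- d$hour - 10
  mu <- cbind(1, tc, tc^2, tc^3) %*% trend
  if (!is.null(ma)) {
    g <- ma[d$subject]
    mu <- mu + g * (beta_snp + delta[1] * tc + delta[2] * tc^2 + delta[3] * tc^3)
  }
  d$sbp <- as.vector(mu) + unlist(lapply(seq_len(n_sub), function(i)
    ar1_series(m, rho, sigma)))
  d$dbp <- d$sbp * 0.6 + rnorm(nrow(d), 0, 1)
  d
}

# A genotype vector guaranteed polymorphic.
draw_ma <- function(n_sub, maf = 0.3) {
  sub <- sprintf("S%03d", seq_len(n_sub))
  repeat {
    ma <- rbinom(n_sub, 2, maf)
    if (length(unique(ma)) > 1) break
  }
  names(ma) <- sub
  ma
}

# Tiny five-sample VCF written by hand, for ingest/recode oracle tests.
write_toy_vcf <- function(path, gts, filters = NULL, ref = "A", alt = "G",
                          multi = FALSE) {
  samples <- paste0("S", seq_along(gts[[1]]))
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FILTER=<ID=LowQual,Description=\"lq\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  if (is.null(filters)) filters <- rep("PASS", length(gts))
  body <- vapply(seq_along(gts), function(i) {
    paste(c("chr1", 100 + i, paste0("rs", i), ref,
            if (multi && i == 1) paste0(alt, ",T") else alt,
            "99", filters[i], paste0("GENE=G", i), "GT", gts[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}
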