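# Independent oracles used across test files. These deliberately take
# different computational routes from the package implementation.

# Exact SD of the clamped, rounded scalar-variability response
# max(1, round(N (1 + b) + eps)), eps ~ Normal(0, wf N), by direct
# enumeration of the discrete response distribution.
oracle_response_sd <- function(N, wf, bias = 0) {
  mu <- N * (1 + bias)
  s <- wf * N
  if (s == 0) return(0)
  hi <- ceiling(mu + 10 * s)
  k <- 1:hi
  p <- pnorm(k + 0.5, mu, s) - pnorm(k - 0.5, mu, s)
  p[1] <- pnorm(1.5, mu, s) # clamp at 1
  p <- p / sum(p)
  m <- sum(k * p)
  sqrt(sum((k - m)^2 * p))
}

# Bias of the sample SD of a normal sample of size n: E[S] = c4 sigma.
c4_const <- function(n) sqrt(2 / (n - 1)) * gamma(n / 2) / gamma((n - 1) / 2)

# Brute-force sums-of-squares one-way repeated-measures ANOVA from first
# principles (explicit loops over marginal means), plus the
# Greenhouse-Geisser epsilon from the double-centred covariance matrix of
# the raw condition scores -- a different derivation from the package's
# orthonormal-contrast projection.
oracle_rm_anova_1f <- function(Y) {
  # Y: subjects x conditions matrix
  n <- nrow(Y); p <- ncol(Y)
  grand <- mean(Y)
  cond_means <- colMeans(Y)
  subj_means <- rowMeans(Y)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_err <- 0
  for (i in 1:n) for (j in 1:p) {
    ss_err <- ss_err +
      (Y[i, j] - cond_means[j] - subj_means[i] + grand)^2
  }
  df1 <- p - 1
  df2 <- (n - 1) * (p - 1)
  Fval <- (ss_cond / df1) / (ss_err / df2)
  # GG epsilon via double-centred covariance of the condition scores
  S <- cov(Y)
  rm <- rowMeans(S); cm <- colMeans(S); gm <- mean(S)
  Sstar <- S - outer(rm, rep(1, p)) - outer(rep(1, p), cm) + gm
  eps <- sum(diag(Sstar))^2 / ((p - 1) * sum(Sstar^2))
  list(F = Fval, df1 = df1, df2 = df2,
       p = pf(Fval, df1, df2, lower.tail = FALSE), eps = eps,
       ss_cond = ss_cond, ss_err = ss_err)
}

# High-resolution quadrature oracle for the JZS Bayes factor via the
# Cauchy-delta marginal (substituting delta = r tan(theta), so the Cauchy
# prior becomes uniform on theta), Simpson's rule.
oracle_jzs_lbf <- function(t, n, r = sqrt(2) / 2, n_grid = 4001) {
  nu <- n - 1
  theta <- seq(-pi / 2 + 1e-5, pi / 2 - 1e-5, length.out = n_grid)
  delta <- r * tan(theta)
  f <- suppressWarnings(dt(t, nu, ncp = delta * sqrt(n))) / pi
  h <- theta[2] - theta[1]
  stopifnot(n_grid %% 2 == 1)
  wts <- c(1, rep(c(4, 2), length.out = n_grid - 2), 1)
  m1 <- sum(wts * f) * h / 3
  log10(m1 / dt(t, nu))
}
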