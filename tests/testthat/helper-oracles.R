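# Shared fixtures and independent oracles used across the suite.

# Printed data sets (collapsed counts y11, yd, y00)
counts_independence <- function() list(mz = twin_counts(6, 1876, 98118),
                                       dz = twin_counts(12, 2007, 97981))
counts_familial <- function() list(mz = twin_counts(12, 47, 3941),
                                   dz = twin_counts(4, 103, 5893))
counts_cleft <- function() list(mz = twin_counts(3, 8, 4474),
                                dz = twin_counts(1, 14, 8164))
counts_ra_danish <- function() list(mz = twin_counts(4, 58, 7517),
                                    dz = twin_counts(2, 126, 11666))
counts_ra_finnish <- function() list(mz = twin_counts(9, 64, 4064),
                                     dz = twin_counts(6, 167, 8983))

# Multinomial log-pmf oracle with the combinatorial constant removed,
# written independently of the package's likelihood path.
oracle_loglik <- function(pi, d_mz, d_dz, y_mz, y_dz) {
  one <- function(delta, y) {
    q <- delta * (1 - pi) + pi
    p <- c(pi * q, 2 * pi * (1 - q), 1 - pi * q - 2 * pi * (1 - q))
    y <- as.numeric(y)
    stats::dmultinom(y, prob = p, log = TRUE) -
      (lgamma(sum(y) + 1) - sum(lgamma(y + 1)))
  }
  one(d_mz, y_mz) + one(d_dz, y_dz)
}

# Lower admissibility bound for delta given pi (all cells in [0, 1]).
delta_lower <- function(pi) max(-pi / (1 - pi), (pi - 1) / pi, -1)

# Draw a random admissible (pi, delta_mz, delta_dz) triple.
random_admissible <- function() {
  pi <- stats::runif(1, 0.01, 0.6)
  lo <- delta_lower(pi)
  c(pi = pi,
    d_mz = stats::runif(1, lo + 0.01, 0.99),
    d_dz = stats::runif(1, lo + 0.01, 0.99))
}

# Brute-force shortest window containing ceiling(mass * n) sorted draws.
hpd_bruteforce <- function(x, mass = 0.95) {
  s <- sort(x)
  n <- length(s)
  m <- ceiling(mass * n)
  best <- c(s[1], s[n])
  for (i in 1:(n - m + 1)) {
    if (s[i + m - 1] - s[i] < best[2] - best[1])
      best <- c(s[i], s[i + m - 1])
  }
  best
}

# Posterior mean of pi by 2-D separable grid integration of the closed-form
# unnormalized posterior (flat priors, natural scale). The likelihood
# factorizes per zygosity given pi, so the two delta integrals are
# one-dimensional.
grid_posterior_mean_pi <- function(y_mz, y_dz, n_pi = 1500, n_delta = 1500) {
  pis <- seq(1e-4, 1 - 1e-4, length.out = n_pi)
  group_integral <- function(pi, y) {
    lo <- delta_lower(pi)
    ds <- seq(lo + 1e-9, 1 - 1e-9, length.out = n_delta)
    q <- ds * (1 - pi) + pi
    p11 <- pi * q
    pd <- 2 * pi * (1 - q)
    p00 <- 1 - p11 - pd
    ll <- ifelse(p11 > 0 | y[1] == 0, y[1] * log(pmax(p11, 1e-300)), -Inf) +
      ifelse(pd > 0 | y[2] == 0, y[2] * log(pmax(pd, 1e-300)), -Inf) +
      ifelse(p00 > 0 | y[3] == 0, y[3] * log(pmax(p00, 1e-300)), -Inf)
    mx <- max(ll)
    if (!is.finite(mx)) return(-Inf)
    mx + log(sum(exp(ll - mx)) * (ds[2] - ds[1]))
  }
  y_mz <- as.numeric(y_mz)
  y_dz <- as.numeric(y_dz)
  lw <- vapply(pis, function(p)
    group_integral(p, y_mz) + group_integral(p, y_dz), numeric(1))
  w <- exp(lw - max(lw))
  sum(pis * w) / sum(w)
}

# Batch-means Monte-Carlo standard error for an autocorrelated chain.
batch_se <- function(x, n_batch = 50) {
  n <- length(x)
  bs <- floor(n / n_batch)
  means <- vapply(seq_len(n_batch),
                  function(b) mean(x[((b - 1) * bs + 1):(b * bs)]),
                  numeric(1))
  stats::sd(means) / sqrt(n_batch)
}
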