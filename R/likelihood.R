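#' Multinomial log likelihood of two zygosity groups
#'
#' The data likelihood is proportional to the product of two multinomials,
#' one per zygosity, sharing the prevalence but with separate dependence
#' differences. The multinomial coefficient is dropped (it does not involve
#' the parameters). Cells with probability zero contribute nothing when the
#' corresponding count is zero (`0 * log 0 = 0`) and `-Inf` otherwise.
#'
#' @param pi Prevalence in (0, 1).
#' @param delta_mz,delta_dz Dependence differences.
#' @param y_mz,y_dz [twin_counts()] vectors for MZ and DZ pairs.
#' @return The log likelihood up to an additive constant; `-Inf` for
#'   inadmissible parameters.
#' @export
log_likelihood <- function(pi, delta_mz, delta_dz, y_mz, y_dz) {
  y_mz <- as_twin_counts(y_mz)
  y_dz <- as_twin_counts(y_dz)
  if (!isTRUE(constraint_ok(pi, delta_mz)) ||
      !isTRUE(constraint_ok(pi, delta_dz))) return(-Inf)
  ll_group(pi, delta_mz, y_mz) + ll_group(pi, delta_dz, y_dz)
}

ll_group <- function(pi, delta, y) {
  q <- delta * (1 - pi) + pi
  p <- c(pi * q, 2 * pi * (1 - q), 1 + pi * (q - 2))
  s <- 0
  for (k in 1:3) {
    if (y[[k]] > 0) {
      if (p[k] <= 0) return(-Inf)
      s <- s + y[[k]] * log(p[k])
    }
  }
  s
}

#' Log joint posterior on the transformed scale
#'
#' Unnormalized log posterior density of `(lambda, mu_mz, mu_dz)`: the Beta
#' prior term in `pi(lambda)`, the two scaled-Beta prior terms in
#' `delta(mu)`, the three change-of-variable Jacobian factors
#' `exp(lambda)/(1+exp(lambda))^2` and `exp(mu)/(1+exp(mu))^2`, and the
#' multinomial log likelihood. Points whose back-transformed parameters
#' violate the positive-cell constraint evaluate to `-Inf`, which makes a
#' Metropolis-Hastings proposal there certain to be rejected — the
#' stay-at-current-value rule for the truncation.
#'
#' @param theta Numeric vector `(lambda, mu_mz, mu_dz)`.
#' @param y_mz,y_dz [twin_counts()] vectors.
#' @param prior A [twin_prior()].
#' @return Log posterior density up to an additive constant (`-Inf` allowed,
#'   never `NaN`).
#' @export
log_posterior <- function(theta, y_mz, y_dz, prior = twin_prior()) {
  f <- make_log_posterior(as_twin_counts(y_mz), as_twin_counts(y_dz), prior)
  f(as.numeric(theta))
}

# Closure evaluated hundreds of thousands of times inside the sampler:
# unpack everything once, keep the body to plain arithmetic.
make_log_posterior <- function(y_mz, y_dz, prior) {
  stopifnot(inherits(prior, "twin_prior"))
  y1m <- y_mz[[1]]; ydm <- y_mz[[2]]; y0m <- y_mz[[3]]
  y1d <- y_dz[[1]]; ydd <- y_dz[[2]]; y0d <- y_dz[[3]]
  a1 <- prior$a1; a2 <- prior$a2
  b1 <- prior$b1; b2 <- prior$b2
  g1 <- prior$g1; g2 <- prior$g2
  function(theta) {
    if (any(!is.finite(theta))) return(-Inf)
    pi <- 1 / (1 + exp(-theta[1]))
    dm <- tanh(theta[2] / 2)
    dd <- tanh(theta[3] / 2)
    qm <- dm * (1 - pi) + pi
    qd <- dd * (1 - pi) + pi
    lo <- 2 - 1 / pi
    if (qm < 0 || qm > 1 || qm < lo || qd < 0 || qd > 1 || qd < lo)
      return(-Inf)
    # log prior (shape terms only; normalizing constants dropped)
    lp <- (a1 - 1) * log(pi) + (a2 - 1) * log1p(-pi) +
      (b1 - 1) * log1p(dm) + (b2 - 1) * log1p(-dm) +
      (g1 - 1) * log1p(dd) + (g2 - 1) * log1p(-dd)
    # log Jacobians: exp(l)/(1+exp(l))^2 = pi(1-pi); for mu, (1-delta^2)/4
    lp <- lp + log(pi) + log1p(-pi) +
      log1p(-dm * dm) + log1p(-dd * dd) - 2 * log(4)
    # log likelihood, 0*log(0) := 0
    p <- c(pi * qm, 2 * pi * (1 - qm), 1 + pi * (qm - 2),
           pi * qd, 2 * pi * (1 - qd), 1 + pi * (qd - 2))
    y <- c(y1m, ydm, y0m, y1d, ydd, y0d)
    for (k in 1:6) {
      if (y[k] > 0) {
        if (p[k] <= 0) return(-Inf)
        lp <- lp + y[k] * log(p[k])
      }
    }
    if (is.nan(lp)) return(-Inf)
    lp
  }
}
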