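#' Back-transform a chain to natural parameters and derived quantities
#'
#' Applies the inverse logit-style transforms to every draw and derives the
#' casewise concordance rates `q = delta * (1 - pi) + pi` per zygosity plus
#' the three contrasts of interest: `q_mz - q_dz` (evidence for a genetic
#' component), `q_mz - pi` and `q_dz - pi` (evidence for familial
#' clustering).
#'
#' @param chain A `"twin_chain"` object or an n x 3 matrix of
#'   `(lambda, mu_mz, mu_dz)` draws.
#' @return A data frame with one row per draw and columns `pi`, `delta_mz`,
#'   `delta_dz`, `q_mz`, `q_dz`, `q_mz_minus_q_dz`, `q_mz_minus_pi`,
#'   `q_dz_minus_pi`.
#' @export
backtransform <- function(chain) {
  th <- if (inherits(chain, "twin_chain")) chain$draws else as.matrix(chain)
  if (nrow(th) < 1L) stop("empty chain")
  pi <- stats::plogis(th[, 1])
  dmz <- tanh(th[, 2] / 2)
  ddz <- tanh(th[, 3] / 2)
  q_mz <- dmz * (1 - pi) + pi
  q_dz <- ddz * (1 - pi) + pi
  data.frame(pi = pi, delta_mz = dmz, delta_dz = ddz,
             q_mz = q_mz, q_dz = q_dz,
             q_mz_minus_q_dz = q_mz - q_dz,
             q_mz_minus_pi = q_mz - pi,
             q_dz_minus_pi = q_dz - pi)
}

#' Highest posterior density interval
#'
#' The shortest contiguous interval containing a fraction `mass` of the
#' draws: over the sorted sample, the window of `ceiling(mass * n)`
#' consecutive order statistics with the smallest width.
#'
#' @param x Numeric vector of posterior draws.
#' @param mass Probability mass of the interval, in (0, 1); default 0.95.
#' @return Named numeric vector `(lower, upper)`.
#' @examples
#' set.seed(1)
#' hpd_interval(rnorm(10000))  # close to (-1.96, 1.96)
#' @export
hpd_interval <- function(x, mass = 0.95) {
  stopifnot(is.numeric(x), mass > 0, mass < 1)
  n <- length(x)
  if (n < ceiling(1 / (1 - mass)))
    stop("need at least ", ceiling(1 / (1 - mass)),
         " draws for mass = ", mass)
  m <- ceiling(mass * n)
  s <- sort(x)
  if (m >= n) return(c(lower = s[1], upper = s[n]))
  widths <- s[m:n] - s[1:(n - m + 1L)]
  i <- which.min(widths)
  c(lower = s[i], upper = s[i + m - 1L])
}

#' Posterior summary table for a set of draws
#'
#' Sample mean, standard deviation, median, and highest posterior density
#' interval for each column of a draws data frame.
#'
#' @param draws A data frame of per-draw quantities, e.g. from
#'   [backtransform()].
#' @param mass HPD mass (default 0.95).
#' @return A data frame with columns `mean`, `sd`, `median`, `hpd_lower`,
#'   `hpd_upper` and one row per quantity.
#' @export
summarize_draws <- function(draws, mass = 0.95) {
  stopifnot(is.data.frame(draws), nrow(draws) >= 1L)
  out <- t(vapply(draws, function(v) {
    h <- hpd_interval(v, mass)
    c(mean = mean(v), sd = stats::sd(v), median = stats::median(v),
      hpd_lower = h[["lower"]], hpd_upper = h[["upper"]])
  }, numeric(5)))
  as.data.frame(out)
}

#' Posterior probability that one quantity exceeds another
#'
#' The fraction of draws with `a > b` (strict); `b` may be a scalar
#' threshold or a second draw sequence of equal length.
#'
#' @param a Numeric draws.
#' @param b Numeric draws of the same length, or a single number.
#' @return A fraction in \[0, 1\].
#' @examples
#' # P(q_MZ - q_DZ > 0.04) from a fitted model `fit`:
#' # prob_exceeds(backtransform(fit$chain)$q_mz_minus_q_dz, 0.04)
#' @export
prob_exceeds <- function(a, b) {
  if (length(b) != 1L && length(b) != length(a))
    stop("b must be a scalar or match the length of a")
  mean(a > b)
}

#' Summaries under the normal (Laplace) approximation
#'
#' Draws a large sample from the multivariate normal approximation
#' `N(mode, cov)` in the transformed space, back-transforms it, and
#' summarizes like the MCMC output. Used to compare the exact posterior with
#' its normal approximation: for rare traits the approximation is adequate
#' for the prevalence but visibly too symmetric for the concordance rates.
#'
#' @param fit A `"twin_laplace"` object.
#' @param n_draws Size of the normal sample (default 100000).
#' @param seed Integer seed.
#' @param mass HPD mass.
#' @return A summary data frame as from [summarize_draws()].
#' @export
normal_approx_summary <- function(fit, n_draws = 100000L, seed = 1L,
                                  mass = 0.95) {
  stopifnot(inherits(fit, "twin_laplace"))
  ev <- eigen(fit$cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < 0))
    stop("covariance is not positive semi-definite")
  set.seed(as.integer(seed))
  th <- MASS::mvrnorm(n_draws, mu = fit$mode, Sigma = fit$cov)
  summarize_draws(backtransform(th), mass)
}
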