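#' Random-walk Metropolis-Hastings sampler
#'
#' Samples the transformed posterior with a multivariate normal random-walk
#' proposal centred at the current state. By default the proposal covariance
#' is the Laplace-approximation posterior covariance and the chain starts at
#' the Laplace mode. Proposals outside the admissible region have log
#' posterior `-Inf` and are rejected, so the chain stays put there.
#'
#' Randomness contract: `set.seed(seed)` is called once, then all
#' `3 * n_iter` proposal increments are drawn (row-wise), then the `n_iter`
#' uniform acceptance variates; runs are therefore bit-reproducible for a
#' given seed and package version.
#'
#' @inheritParams log_posterior
#' @param n_iter Number of iterations (>= 1).
#' @param seed Integer seed; required, no silent default.
#' @param proposal_cov Optional 3x3 proposal covariance; defaults to the
#'   Laplace covariance.
#' @param proposal_scale Scalar multiplier on the proposal covariance
#'   (default 1, i.e. the Laplace covariance used as-is).
#' @param start Optional starting value `(lambda, mu_mz, mu_dz)`; defaults
#'   to the Laplace mode.
#' @param laplace Optional precomputed [laplace_approx()] fit.
#' @return An object of class `"twin_chain"`: list with `draws` (n_iter x 3
#'   matrix of `(lambda, mu_mz, mu_dz)`), `acceptance_rate`, `n_iter`,
#'   `seed`, `laplace`.
#' @export
run_mh <- function(y_mz, y_dz, prior = twin_prior(), n_iter = 100000L,
                   seed, proposal_cov = NULL, proposal_scale = 1,
                   start = NULL, laplace = NULL) {
  y_mz <- as_twin_counts(y_mz)
  y_dz <- as_twin_counts(y_dz)
  if (missing(seed) || is.null(seed))
    stop("an integer 'seed' is required for a reproducible chain")
  n_iter <- as.integer(n_iter)
  stopifnot(n_iter >= 1L, proposal_scale > 0)
  if (is.null(proposal_cov) || is.null(start)) {
    if (is.null(laplace)) laplace <- laplace_approx(y_mz, y_dz, prior)
    if (is.null(proposal_cov)) proposal_cov <- laplace$cov
    if (is.null(start)) start <- laplace$mode
  }
  f <- make_log_posterior(y_mz, y_dz, prior)
  lp_cur <- f(start)
  if (!is.finite(lp_cur))
    stop("log posterior is not finite at the starting value")

  set.seed(as.integer(seed))
  R <- chol(proposal_scale * proposal_cov)
  steps <- matrix(stats::rnorm(3L * n_iter), n_iter, 3L) %*% R
  logu <- log(stats::runif(n_iter))

  draws <- matrix(NA_real_, n_iter, 3L,
                  dimnames = list(NULL, c("lambda", "mu_mz", "mu_dz")))
  cur <- as.numeric(start)
  acc <- 0L
  for (i in seq_len(n_iter)) {
    prop <- cur + steps[i, ]
    lp <- f(prop)
    if (logu[i] < lp - lp_cur) {
      cur <- prop
      lp_cur <- lp
      acc <- acc + 1L
    }
    draws[i, ] <- cur
  }
  structure(list(draws = draws, acceptance_rate = acc / n_iter,
                 n_iter = n_iter, seed = as.integer(seed),
                 laplace = laplace, prior = prior,
                 counts = list(mz = y_mz, dz = y_dz)),
            class = "twin_chain")
}

#' @export
print.twin_chain <- function(x, ...) {
  cat("Metropolis-Hastings chain: ", x$n_iter, " iterations, acceptance rate ",
      round(x$acceptance_rate, 3), ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Sample autocorrelation of a chain component
#'
#' Standard sample autocorrelation (lag 0 = 1) of one parameter's chain,
#' a basic mixing diagnostic.
#'
#' @param x A `"twin_chain"` object or a numeric vector.
#' @param parameter Column index or name when `x` is a chain (default 1).
#' @param max_lag Largest lag to compute; must be smaller than the chain
#'   length.
#' @return Numeric vector of autocorrelations at lags `0:max_lag`. For a
#'   constant chain the autocorrelation is undefined and a vector of `NA`s
#'   is returned with a warning.
#' @export
autocorrelation <- function(x, parameter = 1L, max_lag = 50L) {
  v <- if (inherits(x, "twin_chain")) x$draws[, parameter] else as.numeric(x)
  if (length(v) <= max_lag)
    stop("chain length must exceed max_lag")
  if (stats::sd(v) == 0) {
    warning("constant chain: autocorrelation undefined")
    return(rep(NA_real_, max_lag + 1L))
  }
  drop(stats::acf(v, lag.max = max_lag, plot = FALSE,
                  demean = TRUE)$acf)
}
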