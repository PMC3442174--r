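#' Laplace approximation of the joint posterior
#'
#' Finds the mode of the transformed log posterior by numerical
#' optimization (Nelder-Mead, refined with BFGS) and approximates the
#' posterior covariance by the inverse of the negative Hessian at the mode
#' (finite differences). Starting values come from moment estimates: the
#' observed prevalence and the observed casewise concordance rates, clipped
#' into the admissible interior.
#'
#' @inheritParams log_posterior
#' @return An object of class `"twin_laplace"`: list with `mode` (named
#'   `(lambda, mu_mz, mu_dz)`), `cov` (3x3 symmetric positive-definite),
#'   `value` (log posterior at the mode), and `mode_natural`.
#' @examples
#' laplace_approx(twin_counts(6, 1876, 98118), twin_counts(12, 2007, 97981))
#' @export
laplace_approx <- function(y_mz, y_dz, prior = twin_prior()) {
  y_mz <- as_twin_counts(y_mz)
  y_dz <- as_twin_counts(y_dz)
  stopifnot(inherits(prior, "twin_prior"))
  affected <- 2 * (y_mz[["y11"]] + y_dz[["y11"]]) + y_mz[["yd"]] + y_dz[["yd"]]
  if (affected == 0 && prior$a1 <= 1)
    stop("no affected individuals in the data and a flat prevalence prior: ",
         "the posterior mode diverges; supply an informative prevalence prior")
  f <- make_log_posterior(y_mz, y_dz, prior)
  theta0 <- laplace_start(y_mz, y_dz, prior)
  if (!is.finite(f(theta0)))
    stop("internal error: inadmissible starting value for the optimizer")
  neg <- function(th) -f(th)
  opt <- stats::optim(theta0, neg, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  opt2 <- suppressWarnings(
    stats::optim(opt$par, neg, method = "BFGS",
                 control = list(maxit = 200, reltol = 1e-10)))
  if (is.finite(opt2$value) && opt2$value <= opt$value) opt <- opt2
  if (!is.finite(opt$value))
    stop("Laplace approximation failed: optimizer did not reach a finite mode")
  mode <- opt$par
  names(mode) <- c("lambda", "mu_mz", "mu_dz")
  H <- stats::optimHess(mode, neg)
  if (any(!is.finite(H)))
    stop("Laplace approximation failed: non-finite Hessian at the mode")
  H <- (H + t(H)) / 2
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stop("Laplace approximation failed: Hessian not positive definite ",
         "(eigenvalues ", paste(signif(ev, 3), collapse = ", "), "); ",
         "the mode may lie on the constraint boundary")
  cov <- solve(H)
  cov <- (cov + t(cov)) / 2
  dimnames(cov) <- list(names(mode), names(mode))
  structure(list(mode = mode, cov = cov, value = -opt$value,
                 mode_natural = from_real(mode),
                 counts = list(mz = y_mz, dz = y_dz), prior = prior),
            class = "twin_laplace")
}

# Moment-estimate starting point, clipped well inside the admissible region.
laplace_start <- function(y_mz, y_dz, prior) {
  n_tot <- sum(y_mz) + sum(y_dz)
  affected <- 2 * (y_mz[["y11"]] + y_dz[["y11"]]) + y_mz[["yd"]] + y_dz[["yd"]]
  pi0 <- affected / (2 * n_tot)
  if (pi0 <= 0) pi0 <- (prior$a1) / (prior$a1 + prior$a2)  # prior mean-ish
  pi0 <- min(max(pi0, 1e-6), 1 - 1e-6)
  d0 <- function(y) {
    r <- empirical_rates(y)
    q <- if (is.na(r$concordance)) pi0 else r$concordance
    d <- (q - pi0) / (1 - pi0)
    lo <- max(-pi0 / (1 - pi0), (pi0 - 1) / pi0, -1)
    min(max(d, lo * 0.999 + 1e-8), 0.999)
  }
  to_real(pi0, d0(y_mz), d0(y_dz))
}

#' @export
print.twin_laplace <- function(x, digits = 4, ...) {
  cat("Laplace approximation of the twin-concordance posterior\n")
  nat <- x$mode_natural
  cat("  mode (natural scale): pi =", signif(nat[["pi"]], digits),
      " delta_MZ =", signif(nat[["delta_mz"]], digits),
      " delta_DZ =", signif(nat[["delta_dz"]], digits), "\n")
  cat("  posterior SDs (transformed scale):",
      paste(signif(sqrt(diag(x$cov)), digits), collapse = ", "), "\n")
  invisible(x)
}
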