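#' Prior hyperparameters
#'
#' The prevalence prior is `pi ~ Beta(a1, a2)`; each dependence difference
#' has a truncated scaled Beta prior on \[-1, 1\] with shapes `(b1, b2)` for
#' MZ pairs and `(g1, g2)` for DZ pairs, truncated to the admissible region
#' where all cell probabilities are non-negative. All shapes equal to 1 is
#' the non-informative default.
#'
#' @param a1,a2 Prevalence Beta shapes (> 0).
#' @param b1,b2 MZ dependence scaled-Beta shapes (> 0).
#' @param g1,g2 DZ dependence scaled-Beta shapes (> 0).
#' @return An object of class `"twin_prior"`.
#' @examples
#' twin_prior()                 # flat
#' twin_prior(a1 = 1334, a2 = 355154)
#' @export
twin_prior <- function(a1 = 1, a2 = 1, b1 = 1, b2 = 1, g1 = 1, g2 = 1) {
  h <- c(a1 = a1, a2 = a2, b1 = b1, b2 = b2, g1 = g1, g2 = g2)
  if (anyNA(h) || any(h <= 0))
    stop("all hyperparameters must be strictly positive")
  structure(as.list(h), class = "twin_prior")
}

#' @export
print.twin_prior <- function(x, ...) {
  cat("Prior: pi ~ Beta(", x$a1, ", ", x$a2, ")",
      if (x$a1 == 1 && x$a2 == 1) " [flat]", "\n",
      "       delta_MZ ~ scaled Beta(", x$b1, ", ", x$b2, ") on [-1, 1]\n",
      "       delta_DZ ~ scaled Beta(", x$g1, ", ", x$g2, ") on [-1, 1]\n",
      sep = "")
  invisible(x)
}

#' Informative prevalence prior from a prevalence study
#'
#' A prevalence study observing `n_affected` cases among `n_total`
#' individuals yields the conjugate update of the flat Beta(1, 1) prior:
#' `pi ~ Beta(1 + n_affected, 1 + n_total - n_affected)`. The dependence
#' shapes of `prior` are left untouched.
#'
#' @param n_affected Number of affected individuals in the study.
#' @param n_total Total number of individuals in the study.
#' @param prior A [twin_prior()] whose dependence shapes to keep.
#' @return A [twin_prior()] with updated `a1`, `a2`.
#' @examples
#' prevalence_prior(1693, 2524359)  # Beta(1694, 2522667)
#' @export
prevalence_prior <- function(n_affected, n_total, prior = twin_prior()) {
  stopifnot(inherits(prior, "twin_prior"))
  if (anyNA(c(n_affected, n_total)) || n_affected < 0 || n_total < n_affected)
    stop("need 0 <= n_affected <= n_total")
  prior$a1 <- 1 + n_affected
  prior$a2 <- 1 + (n_total - n_affected)
  prior
}
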