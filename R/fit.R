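#' Fit the Bayesian twin-concordance model
#'
#' Main entry point. Given the collapsed twin-pair counts of the two
#' zygosity groups, fits the three-parameter model (prevalence `pi`,
#' dependence differences `delta_MZ`, `delta_DZ`) by random-walk
#' Metropolis-Hastings on the logit-transformed parameters, started at the
#' Laplace-approximation posterior mode with the Laplace covariance as
#' proposal covariance.
#'
#' @param mz,dz [twin_counts()] vectors (or length-3 numerics) for the MZ
#'   and DZ groups.
#' @param prior A [twin_prior()]; the default is flat (all shapes 1).
#' @param n_iter Number of MH iterations (default 100000).
#' @param burn_in Iterations discarded before summarizing (default 0: the
#'   chain already starts at the posterior mode).
#' @param seed Integer seed, required.
#' @param hpd_mass Mass of reported HPD intervals (default 0.95).
#' @param proposal_cov,proposal_scale Proposal covariance (default: Laplace)
#'   and a scalar multiplier on it (default 1).
#' @return An object of class `"twin_fit"` with components `chain`
#'   (`"twin_chain"`), `laplace`, `draws` (post-burn-in back-transformed
#'   draws from [backtransform()]), `acceptance_rate`, `counts`, `prior`,
#'   `seed`, `n_iter`, `burn_in`, `hpd_mass`.
#' @examples
#' fit <- twin_fit(mz = c(3, 8, 4474), dz = c(1, 14, 8164),
#'                 n_iter = 5000, seed = 1)
#' summary(fit)
#' @export
twin_fit <- function(mz, dz, prior = twin_prior(), n_iter = 100000L,
                     burn_in = 0L, seed, hpd_mass = 0.95,
                     proposal_cov = NULL, proposal_scale = 1) {
  if (missing(seed) || is.null(seed))
    stop("an integer 'seed' is required for a reproducible fit")
  stopifnot(hpd_mass > 0, hpd_mass < 1, burn_in >= 0, burn_in < n_iter)
  mz <- as_twin_counts(mz)
  dz <- as_twin_counts(dz)
  chain <- run_mh(mz, dz, prior = prior, n_iter = n_iter, seed = seed,
                  proposal_cov = proposal_cov,
                  proposal_scale = proposal_scale)
  keep <- if (burn_in > 0) chain$draws[-seq_len(burn_in), , drop = FALSE]
          else chain$draws
  structure(list(chain = chain, laplace = chain$laplace,
                 draws = backtransform(keep),
                 acceptance_rate = chain$acceptance_rate,
                 counts = list(mz = mz, dz = dz), prior = prior,
                 seed = as.integer(seed), n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), hpd_mass = hpd_mass),
            class = "twin_fit")
}

#' @export
print.twin_fit <- function(x, ...) {
  cat("Bayesian twin-concordance model\n")
  cat("  MZ pairs: ", sum(x$counts$mz), "  DZ pairs: ", sum(x$counts$dz),
      "\n", sep = "")
  cat("  ", x$n_iter, " MH iterations (burn-in ", x$burn_in,
      "), acceptance rate ", round(x$acceptance_rate, 3), "\n", sep = "")
  m <- colMeans(x$draws)
  cat("  posterior means: pi = ", sprintf("%.4g", m[["pi"]]),
      " (", sprintf("%.2f", 100 * m[["pi"]]), "%)",
      "  q_MZ = ", sprintf("%.3f", m[["q_mz"]]),
      "  q_DZ = ", sprintf("%.3f", m[["q_dz"]]), "\n", sep = "")
  cat("Use summary() for the full posterior table.\n")
  invisible(x)
}

#' Posterior summary table of a fitted model
#'
#' @param object A `"twin_fit"`.
#' @param mass HPD mass; defaults to the mass chosen at fit time.
#' @param ... Unused.
#' @return A `"summary.twin_fit"` data frame (rows: `pi`, `q_mz`, `q_dz`,
#'   `q_mz_minus_q_dz`, `q_mz_minus_pi`, `q_dz_minus_pi`, `delta_mz`,
#'   `delta_dz`; columns: mean, sd, median, HPD bounds) at full precision;
#'   the print method renders the prevalence rows in percent.
#' @export
summary.twin_fit <- function(object, mass = object$hpd_mass, ...) {
  ord <- c("pi", "q_mz", "q_dz", "q_mz_minus_q_dz",
           "q_mz_minus_pi", "q_dz_minus_pi", "delta_mz", "delta_dz")
  s <- summarize_draws(object$draws[ord], mass)
  attr(s, "hpd_mass") <- mass
  attr(s, "acceptance_rate") <- object$acceptance_rate
  class(s) <- c("summary.twin_fit", "data.frame")
  s
}

#' @export
print.summary.twin_fit <- function(x, ...) {
  mass <- attr(x, "hpd_mass")
  cat("Posterior summaries (",
      format(100 * mass), "% HPD intervals)\n", sep = "")
  fmt_row <- function(name, r, pct) {
    f <- if (pct) function(v) sprintf("%.2f%%", 100 * v)
         else function(v) sprintf("%.2f", v)
    cat(sprintf("  %-16s mean %s  sd %s  median %s  HPD (%s, %s)\n",
                name, f(r[["mean"]]), f(r[["sd"]]), f(r[["median"]]),
                f(r[["hpd_lower"]]), f(r[["hpd_upper"]])))
  }
  labels <- c(pi = "pi", q_mz = "q_MZ", q_dz = "q_DZ",
              q_mz_minus_q_dz = "q_MZ - q_DZ",
              q_mz_minus_pi = "q_MZ - pi", q_dz_minus_pi = "q_DZ - pi",
              delta_mz = "delta_MZ", delta_dz = "delta_DZ")
  for (nm in rownames(x))
    fmt_row(labels[[nm]], x[nm, ], pct = (nm == "pi"))
  invisible(x)
}

#' @export
coef.twin_fit <- function(object, ...) {
  m <- colMeans(object$draws)
  m[c("pi", "delta_mz", "delta_dz", "q_mz", "q_dz")]
}

#' Posterior density plots with normal-approximation overlay
#'
#' Kernel density estimates of the marginal posteriors of the prevalence
#' and the two concordance rates (black), overlaid with the corresponding
#' marginals of the Laplace normal approximation (gray). For rare traits the
#' concordance-rate posteriors are right-skewed and the normal approximation
#' visibly misses them.
#'
#' @param x A `"twin_fit"`.
#' @param which Quantities to plot (subset of the columns of `x$draws`).
#' @param n_normal Size of the normal-approximation sample.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.twin_fit <- function(x, which = c("pi", "q_mz", "q_dz"),
                          n_normal = 20000L, ...) {
  set.seed(x$seed)
  thn <- MASS::mvrnorm(n_normal, mu = x$laplace$mode, Sigma = x$laplace$cov)
  approx_draws <- backtransform(thn)
  op <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(op))
  labels <- c(pi = "prevalence", q_mz = "q_MZ", q_dz = "q_DZ",
              q_mz_minus_q_dz = "q_MZ - q_DZ")
  for (w in which) {
    d1 <- stats::density(x$draws[[w]])
    d2 <- stats::density(approx_draws[[w]])
    graphics::plot(d1, main = labels[w] %||% w, xlab = w,
                   ylim = range(0, d1$y, d2$y), ...)
    graphics::lines(d2, col = "gray")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Posterior-predictive twin-pair data sets
#'
#' Simulates new count vectors from the fitted model: for each requested
#' replicate a posterior draw `(pi, delta_mz, delta_dz)` is selected at
#' random and one multinomial sample of the original size is drawn per
#' zygosity.
#'
#' @param object A `"twin_fit"`.
#' @param nsim Number of replicate data sets.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of `nsim` lists, each with `mz` and `dz`
#'   [twin_counts()] vectors.
#' @export
simulate.twin_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  idx <- sample.int(nrow(object$draws), nsim, replace = TRUE)
  lapply(idx, function(i) {
    d <- object$draws[i, ]
    list(mz = draw_counts(sum(object$counts$mz), d$pi, d$delta_mz),
         dz = draw_counts(sum(object$counts$dz), d$pi, d$delta_dz))
  })
}
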