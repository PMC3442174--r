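#' Twin-pair count vector
#'
#' Construct the collapsed three-cell count vector for one zygosity group:
#' the number of pairs with both twins affected (`y11`), with exactly one
#' twin affected (`yd`, the discordant pairs), and with neither affected
#' (`y00`). Collapsing the two discordant cells assumes twins within a pair
#' are exchangeable (no birth-order effect).
#'
#' @param y11 Non-negative integer, pairs with both twins affected.
#' @param yd Non-negative integer, discordant pairs.
#' @param y00 Non-negative integer, pairs with both twins healthy.
#' @return An object of class `"twin_counts"`: a named integer vector with
#'   elements `y11`, `yd`, `y00`.
#' @examples
#' twin_counts(3, 8, 4474)
#' @export
twin_counts <- function(y11, yd, y00) {
  y <- c(y11 = y11, yd = yd, y00 = y00)
  if (length(y) != 3L || anyNA(y) || !is.numeric(y))
    stop("counts must be three non-negative integers (y11, yd, y00)")
  if (any(y < 0) || any(y != round(y)))
    stop("counts must be non-negative integers, got (",
         paste(y, collapse = ", "), ")")
  if (sum(y) < 1)
    stop("at least one twin pair is required")
  structure(as.integer(round(y)), names = c("y11", "yd", "y00"),
            class = "twin_counts")
}

#' @export
print.twin_counts <- function(x, ...) {
  cat("Twin-pair counts: both affected ", x[["y11"]],
      ", discordant ", x[["yd"]],
      ", both healthy ", x[["y00"]],
      "  (n = ", sum(x), " pairs)\n", sep = "")
  invisible(x)
}

# Internal coercion. Unlike the user-facing constructor, an all-zero vector
# is admitted: the empty-data likelihood is a well-defined empty product,
# which the sampler exploits for prior-only runs.
as_twin_counts <- function(y) {
  if (inherits(y, "twin_counts")) return(y)
  if (is.numeric(y) && length(y) == 3L) {
    if (all(y == 0))
      return(structure(c(y11 = 0L, yd = 0L, y00 = 0L),
                       class = "twin_counts"))
    return(twin_counts(y[1], y[2], y[3]))
  }
  stop("cannot interpret object as twin-pair counts")
}

#' Pool historical twin studies
#'
#' Combines several twin studies by componentwise addition of their count
#' vectors, separately per zygosity. With flat priors, fitting the pooled
#' counts is equivalent to using the earlier studies' posterior as the prior
#' for the newest study, because the multinomial log likelihood is additive
#' in the counts.
#'
#' @param ... Studies, each a list with elements `mz` and `dz` (each a
#'   [twin_counts()] vector or a length-3 numeric).
#' @param weights Study weights. Only equal (unit) weights are supported;
#'   power-prior style down-weighting is not implemented.
#' @return A list with pooled `mz` and `dz` [twin_counts()] vectors.
#' @examples
#' danish <- list(mz = twin_counts(4, 58, 7517), dz = twin_counts(2, 126, 11666))
#' finnish <- list(mz = twin_counts(9, 64, 4064), dz = twin_counts(6, 167, 8983))
#' pool_counts(danish, finnish)
#' @export
pool_counts <- function(..., weights = NULL) {
  studies <- list(...)
  if (length(studies) == 1L && is.null(studies[[1]]$mz) &&
      is.list(studies[[1]]) && length(studies[[1]]) >= 1L)
    studies <- studies[[1]]
  if (length(studies) < 1L) stop("at least one study is required")
  if (!is.null(weights) && !all(weights == 1))
    stop("power-prior weighting of historical studies is not implemented; ",
         "only equal (unit) weights are supported")
  mz <- c(0L, 0L, 0L)
  dz <- c(0L, 0L, 0L)
  for (s in studies) {
    if (is.null(s$mz) || is.null(s$dz))
      stop("each study must have 'mz' and 'dz' count vectors")
    mz <- mz + unclass(as_twin_counts(s$mz))
    dz <- dz + unclass(as_twin_counts(s$dz))
  }
  list(mz = twin_counts(mz[1], mz[2], mz[3]),
       dz = twin_counts(dz[1], dz[2], dz[3]))
}

#' Naive moment estimates of prevalence and concordance
#'
#' Computes the observed prevalence `(2 y11 + yd) / (2 n)` and the observed
#' casewise concordance rate `2 y11 / (2 y11 + yd)` from a single count
#' vector. These are used as optimizer starting values and for sanity
#' reporting; they are not the Bayesian estimates.
#'
#' @param y A [twin_counts()] vector.
#' @return A list with `prevalence` and `concordance`. When no individual is
#'   affected, `concordance` is `NA` (undefined).
#' @examples
#' empirical_rates(twin_counts(12, 47, 3941))
#' @export
empirical_rates <- function(y) {
  y <- as_twin_counts(y)
  n <- sum(y)
  affected <- 2 * y[["y11"]] + y[["yd"]]
  prev <- affected / (2 * n)
  conc <- if (affected == 0) NA_real_ else 2 * y[["y11"]] / affected
  list(prevalence = prev, concordance = conc)
}
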