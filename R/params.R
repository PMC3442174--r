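#' Casewise concordance rate from prevalence and dependence
#'
#' The model parametrizes within-pair association by the dependence
#' difference `delta = P(affected | co-twin affected) -
#' P(affected | co-twin not affected)`, a label-invariant measure that is
#' zero under independence. The casewise concordance rate follows as
#' `q = delta * (1 - pi) + pi`.
#'
#' @param pi Prevalence, in (0, 1). Vectorized.
#' @param delta Dependence difference, in \[-1, 1\]. Vectorized.
#' @return The concordance rate `q`, guaranteed in \[0, 1\] for admissible
#'   parameters.
#' @seealso [delta_from_concordance()], [cell_probs()], [constraint_ok()]
#' @examples
#' concordance(pi = 0.2, delta = 0.5) # 0.6
#' @export
concordance <- function(pi, delta) {
  check_admissible(pi, delta)
  delta * (1 - pi) + pi
}

#' Dependence difference from prevalence and concordance
#'
#' Algebraic inverse of [concordance()]: `delta = (q - pi) / (1 - pi)`.
#' Needed to set up simulation scenarios stated in terms of concordance
#' rates.
#'
#' @param pi Prevalence, in (0, 1).
#' @param q Concordance rate, in \[0, 1\].
#' @return The dependence difference `delta`.
#' @examples
#' delta_from_concordance(pi = 0.01, q = 0.40) # 0.3939...
#' @export
delta_from_concordance <- function(pi, q) {
  stopifnot(is.numeric(pi), is.numeric(q))
  if (any(pi <= 0 | pi >= 1))
    stop("prevalence must lie strictly between 0 and 1")
  if (any(q < 0 | q > 1))
    stop("concordance rate must lie in [0, 1]")
  (q - pi) / (1 - pi)
}

#' Multinomial cell probabilities of the twin-pair table
#'
#' Maps `(pi, delta)` to the probabilities of the three collapsed cells:
#' `p11 = pi * q`, `pd = 2 * pi * (1 - q)`, `p00 = 1 + pi * (q - 2)`, where
#' `q` is the casewise concordance rate. The components sum to one.
#'
#' @inheritParams concordance
#' @return A named numeric vector `(p11, pd, p00)`.
#' @examples
#' cell_probs(pi = 0.01, delta = 0)  # independence: p11 = pi^2
#' @export
cell_probs <- function(pi, delta) {
  check_admissible(pi, delta)
  q <- delta * (1 - pi) + pi
  c(p11 = pi * q, pd = 2 * pi * (1 - q), p00 = 1 + pi * (q - 2))
}

#' Admissibility of a (prevalence, dependence) pair
#'
#' A pair is admissible when all three implied cell probabilities lie in
#' \[0, 1\], i.e. when the concordance rate `q = delta * (1 - pi) + pi`
#' satisfies `max(0, 2 - 1/pi) <= q <= 1`. For pi >= 1/2 this reduces to
#' the dependence bound `delta > (pi - 1) / pi`; for rarer traits the
#' binding requirement is `q >= 0`, which is strictly stronger.
#'
#' @inheritParams concordance
#' @return Logical; `TRUE` iff the implied cell probabilities are valid.
#' @examples
#' constraint_ok(0.5, -0.5)   # TRUE: bound is -1
#' constraint_ok(0.1, -0.95)  # FALSE: implied q < 0
#' @export
constraint_ok <- function(pi, delta) {
  stopifnot(is.numeric(pi), is.numeric(delta))
  q <- delta * (1 - pi) + pi
  pi > 0 & pi < 1 & delta >= -1 & delta <= 1 &
    q >= 0 & q <= 1 & q >= 2 - 1 / pi
}

check_admissible <- function(pi, delta) {
  if (any(pi <= 0 | pi >= 1))
    stop("prevalence must lie strictly between 0 and 1, got ",
         pi[which(pi <= 0 | pi >= 1)[1]])
  if (any(delta < -1 | delta > 1))
    stop("dependence difference must lie in [-1, 1], got ",
         delta[which(delta < -1 | delta > 1)[1]])
  bad <- !constraint_ok(pi, delta)
  if (any(bad))
    stop("inadmissible parameters: pi = ", pi[which(bad)[1]],
         ", delta = ", delta[which(bad)[1]],
         " implies a negative cell probability",
         " (need delta >= -pi/(1-pi) and delta > (pi-1)/pi)")
  invisible(TRUE)
}

#' Transform natural parameters to the real line
#'
#' The sampler works on `lambda = log(pi / (1 - pi))` (log-odds of the
#' prevalence) and `mu = log((delta + 1) / (1 - delta))` for each zygosity's
#' dependence difference. Both maps are bijections onto the real line.
#'
#' @param pi Prevalence in (0, 1).
#' @param delta_mz,delta_dz Dependence differences in (-1, 1).
#' @return Named numeric vector `(lambda, mu_mz, mu_dz)`.
#' @seealso [from_real()]
#' @export
to_real <- function(pi, delta_mz, delta_dz) {
  if (any(c(pi <= 0, pi >= 1)))
    stop("pi on the boundary of (0, 1) has no finite transform")
  if (any(abs(c(delta_mz, delta_dz)) >= 1))
    stop("delta on the boundary of (-1, 1) has no finite transform")
  c(lambda = log(pi / (1 - pi)),
    mu_mz = log((delta_mz + 1) / (1 - delta_mz)),
    mu_dz = log((delta_dz + 1) / (1 - delta_dz)))
}

#' Back-transform real-line parameters to the natural scale
#'
#' Inverse of [to_real()]: `pi = 1 / (1 + exp(-lambda))` and
#' `delta = (exp(mu) - 1) / (exp(mu) + 1)` (= `tanh(mu / 2)`). Outputs are
#' always inside the open natural ranges; the positive-cell constraint is
#' deliberately not enforced here (it is enforced in the log posterior), so
#' the transform stays a total function.
#'
#' @param theta Numeric vector `(lambda, mu_mz, mu_dz)`, finite.
#' @return Named numeric vector `(pi, delta_mz, delta_dz)`.
#' @export
from_real <- function(theta) {
  stopifnot(is.numeric(theta), length(theta) == 3L, all(is.finite(theta)))
  c(pi = stats::plogis(theta[[1]]),
    delta_mz = tanh(theta[[2]] / 2),
    delta_dz = tanh(theta[[3]] / 2))
}
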