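#' Simulate twin-pair count vectors
#'
#' Generates one data set under the model: for each zygosity group a single
#' multinomial draw of the given number of pairs over the three cells, with
#' cell probabilities implied by the prevalence and the casewise concordance
#' rates. Because twins are exchangeable the split of discordant pairs is
#' irrelevant, so sampling whole pairs is exact.
#'
#' @param pi Prevalence in (0, 1).
#' @param q_mz,q_dz Casewise concordance rates in \[0, 1\]; the implied
#'   dependence differences must be admissible.
#' @param n_mz,n_dz Numbers of MZ and DZ pairs (>= 1).
#' @param seed Integer seed; the MZ group is drawn first, then the DZ group.
#' @return A list with `mz` and `dz` [twin_counts()] vectors and the
#'   scenario settings as attributes.
#' @examples
#' simulate_twin_data(pi = 0.01, q_mz = 0.40, q_dz = 0.10,
#'                    n_mz = 4000, n_dz = 6000, seed = 42)
#' @export
simulate_twin_data <- function(pi, q_mz, q_dz, n_mz, n_dz, seed) {
  stopifnot(n_mz >= 1, n_dz >= 1)
  if (missing(seed) || is.null(seed))
    stop("an integer 'seed' is required for reproducible simulation")
  d_mz <- delta_from_concordance(pi, q_mz)
  d_dz <- delta_from_concordance(pi, q_dz)
  if (!isTRUE(constraint_ok(pi, d_mz)) || !isTRUE(constraint_ok(pi, d_dz)))
    stop("scenario (pi = ", pi, ", q_mz = ", q_mz, ", q_dz = ", q_dz,
         ") implies an inadmissible dependence difference")
  set.seed(as.integer(seed))
  out <- list(mz = draw_counts(n_mz, pi, d_mz),
              dz = draw_counts(n_dz, pi, d_dz))
  attr(out, "scenario") <- list(pi = pi, q_mz = q_mz, q_dz = q_dz,
                                n_mz = n_mz, n_dz = n_dz,
                                seed = as.integer(seed))
  out
}

draw_counts <- function(n, pi, delta) {
  p <- cell_probs(pi, delta)
  y <- stats::rmultinom(1, size = n, prob = p)
  twin_counts(y[1], y[2], y[3])
}
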