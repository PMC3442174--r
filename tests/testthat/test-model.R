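test_that("concordance rate follows q = delta (1 - pi) + pi", {
  expect_equal(concordance(0.01, 0), 0.01)
  expect_equal(concordance(0.3, 1), 1.0)
  expect_equal(concordance(0.2, 0.5), 0.6)
  # strictly increasing in delta for fixed pi
  for (pi in c(0.01, 0.1, 0.4)) {
    lo <- max(-pi / (1 - pi), -1) + 1e-6
    d <- seq(lo, 1, length.out = 50)
    expect_true(all(diff(concordance(pi, d)) > 0))
  }
  expect_error(concordance(0.1, -0.95), "inadmissible")
  expect_error(concordance(1, 0), "strictly between")
})

test_that("delta_from_concordance inverts the concordance map", {
  expect_equal(delta_from_concordance(0.01, 0.01), 0)
  expect_equal(delta_from_concordance(0.2, 0.6), 0.5)
  expect_equal(delta_from_concordance(0.01, 0.40), 0.39 / 0.99)
  set.seed(11)
  for (i in 1:20) {
    p <- random_admissible()
    q <- concordance(p[["pi"]], p[["d_mz"]])
    expect_equal(delta_from_concordance(p[["pi"]], q), p[["d_mz"]],
                 tolerance = 1e-12)
  }
  expect_error(delta_from_concordance(1, 0.5), "strictly between")
})

test_that("cell probabilities match the closed form and sum to one", {
  expect_equal(cell_probs(0.01, 0),
               c(p11 = 1e-4, pd = 0.0198, p00 = 0.9801))
  expect_equal(cell_probs(0.3, 1), c(p11 = 0.3, pd = 0, p00 = 0.7))
  p <- cell_probs(0.01, 0.39 / 0.99)
  expect_equal(unname(p), c(0.004, 0.012, 0.984), tolerance = 1e-12)
  # dense admissible grid: sum to one, label consistency with q
  for (pi in seq(0.005, 0.95, length.out = 25)) {
    lo <- delta_lower(pi)
    for (d in seq(lo + 1e-6, 1, length.out = 25)) {
      p <- cell_probs(pi, d)
      expect_lt(abs(sum(p) - 1), 1e-12)
      q <- concordance(pi, d)
      expect_identical(p[["p11"]], pi * q)
      expect_identical(p[["pd"]], 2 * pi * (1 - q))
    }
  }
  expect_error(cell_probs(0.1, -0.95), "inadmissible")
})

test_that("admissibility is the positive-cell condition", {
  expect_true(constraint_ok(0.5, -0.5))
  expect_false(constraint_ok(0.1, -0.95)) # Eq-4 bound is -9 but q < 0
  expect_true(constraint_ok(0.01, 0))
  expect_true(constraint_ok(0.9, -0.1))
  expect_false(constraint_ok(0.9, -0.2))  # p00 would be negative
  # boundary of the admissible region gives a zero cell, still admissible
  expect_true(constraint_ok(0.2, -0.25))  # q = 0 exactly
})

test_that("real-line transforms round-trip and hit closed forms", {
  expect_equal(unname(to_real(0.5, 0, 0)), c(0, 0, 0))
  expect_equal(to_real(0.01, 0, 0)[["lambda"]], log(0.01 / 0.99))
  expect_equal(to_real(0.5, 0.5, 0)[["mu_mz"]], log(1.5 / 0.5))
  expect_equal(unname(from_real(c(0, 0, 0))), c(0.5, 0, 0))
  expect_equal(from_real(c(log(0.01 / 0.99), 0, 0))[["pi"]], 0.01)
  # asymptotes
  expect_equal(from_real(c(0, 50, -50))[["delta_mz"]], 1, tolerance = 1e-10)
  expect_equal(from_real(c(0, 50, -50))[["delta_dz"]], -1, tolerance = 1e-10)
  # round trip on a grid of admissible parameters
  for (pi in seq(0.01, 0.99, length.out = 15)) {
    for (d in seq(-0.95, 0.95, length.out = 15)) {
      th <- to_real(pi, d, -d / 2)
      nat <- from_real(th)
      expect_equal(unname(nat), c(pi, d, -d / 2), tolerance = 1e-10)
    }
  }
  expect_error(to_real(0, 0, 0), "boundary")
  expect_error(to_real(0.5, 1, 0), "boundary")
})

test_that("log likelihood matches an independent multinomial log-pmf", {
  y0 <- c(0, 0, 0)
  expect_identical(log_likelihood(0.2, 0.1, 0.1, y0, y0), 0)
  # single concordant MZ pair at perfect dependence: p11 = pi
  expect_equal(log_likelihood(0.3, 1, 0, c(1, 0, 0), y0), log(0.3))
  ind <- counts_independence()
  expect_equal(log_likelihood(0.01, 0, 0, ind$mz, ind$dz),
               oracle_loglik(0.01, 0, 0, ind$mz, ind$dz))
  set.seed(7)
  for (i in 1:100) {
    p <- random_admissible()
    y1 <- twin_counts(rpois(1, 3), rpois(1, 10), rpois(1, 50) + 1)
    y2 <- twin_counts(rpois(1, 3), rpois(1, 10), rpois(1, 50) + 1)
    expect_equal(
      log_likelihood(p[["pi"]], p[["d_mz"]], p[["d_dz"]], y1, y2),
      oracle_loglik(p[["pi"]], p[["d_mz"]], p[["d_dz"]], y1, y2),
      tolerance = 1e-9)
  }
  # inadmissible parameters encode as -Inf, not an exception
  expect_identical(log_likelihood(0.1, -0.95, 0, ind$mz, ind$dz), -Inf)
})

test_that("log posterior is Jacobians plus likelihood under flat priors", {
  ind <- counts_independence()
  log_jac <- function(th) {
    nat <- from_real(th)
    log(nat[["pi"]]) + log(1 - nat[["pi"]]) +
      log((1 - nat[["delta_mz"]]^2) / 4) +
      log((1 - nat[["delta_dz"]]^2) / 4)
  }
  for (th in list(c(-4.6, 0.1, -0.2), c(0, 0, 0), c(-2, 1, 0.5))) {
    nat <- from_real(th)
    expect_equal(
      log_posterior(th, ind$mz, ind$dz),
      log_jac(th) + log_likelihood(nat[["pi"]], nat[["delta_mz"]],
                                   nat[["delta_dz"]], ind$mz, ind$dz),
      tolerance = 1e-10)
  }
  # constraint-violating point: pi near 0.9 with strongly negative delta
  th_bad <- to_real(0.9, -0.5, 0)
  expect_identical(log_posterior(th_bad, ind$mz, ind$dz), -Inf)
  # zero data, flat priors: posterior differences are Jacobian ratios
  y0 <- c(0, 0, 0)
  th1 <- c(-1, 0.3, -0.4)
  th2 <- c(0.5, -0.2, 0.8)
  expect_equal(log_posterior(th1, y0, y0) - log_posterior(th2, y0, y0),
               log_jac(th1) - log_jac(th2), tolerance = 1e-10)
})

test_that("informative prior terms enter the log posterior correctly", {
  y0 <- c(0, 0, 0)
  pr <- twin_prior(a1 = 5, a2 = 40, b1 = 2, b2 = 3)
  th <- c(-2, 0.4, -0.1)
  nat <- from_real(th)
  extra <- (5 - 1) * log(nat[["pi"]]) + (40 - 1) * log(1 - nat[["pi"]]) +
    (2 - 1) * log(1 + nat[["delta_mz"]]) +
    (3 - 1) * log(1 - nat[["delta_mz"]])
  expect_equal(log_posterior(th, y0, y0, pr) - log_posterior(th, y0, y0),
               extra, tolerance = 1e-10)
})

test_that("count constructor validates its inputs", {
  expect_error(twin_counts(-1, 0, 5), "non-negative")
  expect_error(twin_counts(0.5, 0, 5), "non-negative integers")
  expect_error(twin_counts(0, 0, 0), "at least one")
  y <- twin_counts(3, 8, 4474)
  expect_s3_class(y, "twin_counts")
  expect_identical(sum(y), 4485L)
})
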