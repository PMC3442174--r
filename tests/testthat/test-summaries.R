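test_that("back-transformation reproduces the natural-scale identities", {
  th <- rbind(c(0, 0, 0), c(-4.59512, 1.09861, -0.5))
  d <- backtransform(th)
  expect_equal(d$pi[1], 0.5)
  expect_equal(d$q_mz[1], 0.5)
  expect_equal(d$q_dz[1], 0.5)
  expect_equal(d$q_mz_minus_q_dz[1], 0)
  expect_equal(d$pi[2], 0.01, tolerance = 1e-5)
  expect_equal(d$delta_mz[2], 0.5, tolerance = 1e-5)
  # per-draw identity q - pi = delta (1 - pi), exact in floating point terms
  set.seed(3)
  thr <- cbind(rnorm(500), rnorm(500), rnorm(500))
  dr <- backtransform(thr)
  expect_equal(dr$q_mz_minus_pi, dr$delta_mz * (1 - dr$pi), tolerance = 1e-14)
  expect_equal(dr$q_dz_minus_pi, dr$delta_dz * (1 - dr$pi), tolerance = 1e-14)
  expect_error(backtransform(matrix(0, 0, 3)), "empty")
})

test_that("HPD equals brute-force shortest-window search for small n", {
  set.seed(8)
  for (rep in 1:40) {
    n <- sample(10:200, 1)
    x <- switch(1 + rep %% 3,
                rnorm(n),
                rexp(n),
                c(rnorm(ceiling(n / 2)), rnorm(floor(n / 2), mean = 6)))
    for (mass in c(0.5, 0.9, 0.95)) {
      if (n < ceiling(1 / (1 - mass))) next
      expect_equal(unname(hpd_interval(x, mass)), hpd_bruteforce(x, mass))
    }
  }
})

test_that("HPD behaves correctly on degenerate and analytic cases", {
  # point mass: zero-width interval at the value
  expect_equal(unname(hpd_interval(rep(3.2, 100))), c(3.2, 3.2))
  # uniform draws: width approximately the mass
  set.seed(12)
  u <- runif(100000)
  h <- hpd_interval(u, 0.95)
  expect_equal(unname(h[2] - h[1]), 0.95, tolerance = 0.01)
  # symmetric unimodal draws: HPD close to the equal-tail interval
  z <- rnorm(100000)
  h2 <- hpd_interval(z, 0.95)
  et <- quantile(z, c(0.025, 0.975))
  expect_equal(unname(h2), unname(et), tolerance = 0.05)
  expect_error(hpd_interval(rnorm(5), 0.95), "at least")
})

test_that("summary tables report mean, sd, median, and HPD mass", {
  const <- data.frame(a = rep(2.5, 1000))
  s <- summarize_draws(const)
  expect_equal(s["a", "mean"], s["a", "median"])
  expect_equal(s["a", "sd"], 0)
  set.seed(4)
  d <- data.frame(x = rnorm(20000), y = rexp(20000))
  s2 <- summarize_draws(d, mass = 0.9)
  # empirical mass inside the interval is at least the nominal mass - 1/n
  for (col in c("x", "y")) {
    inside <- mean(d[[col]] >= s2[col, "hpd_lower"] &
                     d[[col]] <= s2[col, "hpd_upper"])
    expect_gte(inside, 0.9 - 1 / nrow(d))
    expect_lte(s2[col, "hpd_lower"], s2[col, "hpd_upper"])
  }
})

test_that("exceedance probabilities count strict inequalities", {
  x <- rnorm(100)
  expect_equal(prob_exceeds(x, x), 0)
  expect_equal(prob_exceeds(x + 1, x), 1)
  expect_equal(prob_exceeds(c(1, 2, 3, 4), 2.5), 0.5)
  expect_error(prob_exceeds(1:4, 1:3), "length")
})

test_that("normal-approximation summaries match direct logit-normal draws", {
  fit <- structure(list(mode = c(lambda = -2, mu_mz = 0.5, mu_dz = -0.3),
                        cov = diag(c(0.04, 0.09, 0.01))),
                   class = "twin_laplace")
  s <- normal_approx_summary(fit, n_draws = 50000, seed = 2)
  set.seed(99)
  pi_direct <- plogis(rnorm(50000, -2, 0.2))
  expect_equal(s["pi", "mean"], mean(pi_direct), tolerance = 0.01)
  expect_equal(s["pi", "sd"], sd(pi_direct), tolerance = 0.05)
  dmz_direct <- tanh(rnorm(50000, 0.5, 0.3) / 2)
  expect_equal(s["delta_mz", "mean"], mean(dmz_direct), tolerance = 0.01)
  # zero-covariance limit: point mass at the back-transformed mode
  fit0 <- structure(list(mode = c(lambda = -2, mu_mz = 0.5, mu_dz = -0.3),
                         cov = diag(c(0, 0, 0))),
                    class = "twin_laplace")
  s0 <- normal_approx_summary(fit0, n_draws = 1000, seed = 3)
  expect_equal(s0["pi", "mean"], plogis(-2))
  expect_equal(s0["pi", "sd"], 0)
})

test_that("rare-trait concordance posteriors are right-skewed, prevalence not", {
  ind <- counts_independence()
  fit <- twin_fit(ind$mz, ind$dz, n_iter = 30000, seed = 17)
  skew <- function(v) mean((v - mean(v))^3) / sd(v)^3
  expect_gt(skew(fit$draws$q_mz), 0.2)
  expect_gt(skew(fit$draws$q_dz), 0.2)
  expect_lt(abs(skew(fit$draws$pi)), 0.2)
  # the normal approximation is far more symmetric for q than the posterior
  set.seed(18)
  thn <- MASS::mvrnorm(30000, fit$laplace$mode, fit$laplace$cov)
  q_norm <- backtransform(thn)$q_mz
  expect_lt(abs(skew(q_norm)), skew(fit$draws$q_mz) / 2)
})
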