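test_that("mixture constructor enforces invariants", {
  m <- mixture(c(0.25, 0.75), c(0.5, 3))
  expect_equal(m$k, 2)
  expect_equal(sum(m$q), 1)
  expect_error(mixture(c(0.5, 0.6), c(1, 2)), "sum to 1")
  expect_error(mixture(c(0.5, 0.5), c(2, 1)), "increasing")
  expect_error(mixture(c(0.5, 0.5), c(1, 1)), "increasing")
  expect_error(mixture(c(1, 0), c(1, 2)), "positive")
  expect_error(mixture(c(0.5, 0.5), c(-1, 2)), "non-negative")
})

test_that("poisson pmf handles the zero-rate group exactly", {
  expect_equal(poisson_pmf(0, 0), 1)
  expect_equal(poisson_pmf(3, 0), 0)
  expect_equal(poisson_pmf(0, 1), exp(-1))
  expect_error(poisson_pmf(-1, 1))
  expect_error(poisson_pmf(1, -1))
  expect_error(poisson_pmf(1.5, 1))
})

test_that("log-likelihood matches direct summation and is label-invariant", {
  x <- c(0, 1, 2)
  mix <- mixture(c(0.5, 0.5), c(0.5, 2))
  # independent term-by-term evaluation
  direct <- 0
  for (h in x)
    direct <- direct + log(0.5 * exp(-0.5) * 0.5^h / factorial(h) +
                           0.5 * exp(-2) * 2^h / factorial(h))
  expect_equal(loglik_mixture(x, mix), direct, tolerance = 1e-12)

  # k = 1 reduces to the single-Poisson likelihood at its MLE
  set.seed(3)
  y <- rpois(40, 2.3)
  m1 <- mixture(1, mean(y))
  expect_equal(loglik_mixture(y, m1), sum(dpois(y, mean(y), log = TRUE)))

  # component order cannot matter once rates are sorted
  mix_b <- mixture(c(0.5, 0.5), c(0.5, 2))
  expect_identical(loglik_mixture(x, mix), loglik_mixture(x, mix_b))

  expect_equal(loglik_mixture(c(5), mixture(1, 0)), -Inf)
})

test_that("gradient function satisfies NPMLE optimality identities", {
  set.seed(11)
  y <- rpois(60, 1.7)
  m1 <- mixture(1, mean(y))
  # at the single-component MLE, d(lambda_hat) = 1 exactly
  expect_equal(gradient_function(mean(y), y, m1), 1, tolerance = 1e-12)

  # weighted average of d over the support is always 1
  mix <- mixture(c(0.3, 0.7), c(0.5, 3))
  d_sup <- gradient_function(mix$lambda, y, mix)
  expect_equal(sum(mix$q * d_sup), 1, tolerance = 1e-12)

  # a non-optimal mixture on overdispersed data violates sup d <= 1
  z <- c(0, 0, 5)
  bad <- mixture(1, 1)
  d_grid <- gradient_function(seq(0, 6, by = 0.05), z, bad)
  expect_gt(max(d_grid), 1)

  expect_error(gradient_function(-1, y, m1), "non-negative")
})

test_that("NPMLE fit: degenerate inputs", {
  f0 <- fit_npmle(rep(0L, 20))
  expect_equal(f0$mixture$k, 1)
  expect_equal(f0$mixture$lambda, 0)
  expect_equal(f0$loglik, 0)
  expect_true(f0$converged)

  fc <- fit_npmle(rep(3L, 15))
  expect_equal(fc$mixture$k, 1)
  expect_equal(fc$mixture$lambda, 3)

  expect_error(fit_npmle(c(1, 2), grid_size = 1), "grid_size")
})

test_that("NPMLE dominates the single-Poisson MLE and meets the gradient
           condition", {
  set.seed(21)
  for (rep in 1:4) {
    y <- rpois(50, 1)
    f <- fit_npmle(y)
    ll1 <- sum(dpois(y, mean(y), log = TRUE))   # closed-form k=1 oracle
    expect_gte(f$loglik, ll1 - 1e-9)
    if (f$mixture$k == 1) expect_equal(f$loglik, ll1, tolerance = 1e-9)
    expect_lte(f$max_gradient, 1 + 1e-6)
    d_sup <- gradient_function(f$mixture$lambda, y, f$mixture)
    expect_true(all(abs(d_sup - 1) < 1e-4))
  }
})

test_that("NPMLE recovers a well-separated two-group truth", {
  truth <- mixture(c(0.6, 0.4), c(0.2, 4))
  cv <- simulate_counts(truth, 5000, seed = 31)
  f <- fit_npmle(cv)
  expect_true(f$converged)
  # the NPMLE may carry a sliver of tail mass; the dominant support must
  # recover the generating groups
  main <- f$mixture$q > 0.05
  expect_identical(sum(main), 2L)
  expect_equal(f$mixture$lambda[main], truth$lambda, tolerance = 0.15)
  expect_equal(f$mixture$q[main], truth$q, tolerance = 0.05)
  # window metadata propagates
  expect_equal(f$mixture$window, 1)
})

test_that("simulate_counts: reproducibility and moments", {
  m0 <- mixture(1, 0)
  expect_true(all(simulate_counts(m0, 50, seed = 1)$counts == 0))

  m5 <- mixture(1, 5)
  cv <- simulate_counts(m5, 100000, seed = 2)
  expect_lt(abs(mean(cv$counts) - 5), 3 * sqrt(5 / 100000))

  a <- simulate_counts(table4_mixture(), 500, seed = 7)
  b <- simulate_counts(table4_mixture(), 500, seed = 7)
  expect_identical(a$counts, b$counts)
})

test_that("replicate mean count approaches the mixture mean rate", {
  mix <- table4_mixture()
  mean_rate <- sum(mix$q * mix$lambda)   # oracle: weighted rate average
  set.seed(12)
  means <- replicate(50, mean(simulate_counts(mix, 5000)$counts))
  expect_equal(mean(means), mean_rate, tolerance = 0.02)
})

test_that("Poisson rate additivity and time scaling hold on simulation", {
  set.seed(41)
  lam_i <- 1.2; lam_j <- 0.8
  s <- rpois(20000, lam_i) + rpois(20000, lam_j)
  # chi-square GOF of the sum against Poisson(lam_i + lam_j)
  brk <- 0:8
  obs <- tabulate(pmin(s, 8) + 1, nbins = 9)
  p_exp <- c(dpois(0:7, lam_i + lam_j), 1 - ppois(7, lam_i + lam_j))
  gof <- suppressWarnings(chisq.test(obs, p = p_exp))
  expect_gt(gof$p.value, 0.001)

  # k-year window ~ rate k*lambda: compare two-year simulation with the
  # doubled-rate distribution
  two_year <- rpois(20000, lam_i) + rpois(20000, lam_i)
  doubled <- rpois(20000, 2 * lam_i)
  expect_gt(suppressWarnings(
    ks.test(two_year, doubled))$p.value, 0.001)
})

test_that("bootstrap LRT: degenerate and powered cases", {
  # underdispersed data: NPMLE is the single Poisson, statistic 0, p = 1
  x <- rep(c(0L, 1L), 25)
  g <- bootstrap_lrt(x, k_null = 1, n_boot = 19, seed = 3)
  expect_equal(g$statistic, 0)
  expect_equal(g$p_value, 1)

  expect_error(bootstrap_lrt(x, k_null = 1, n_boot = 10), "19")

  # well-separated two-component truth: k_null = 1 strongly rejected
  truth <- mixture(c(0.5, 0.5), c(0.2, 6))
  cv <- simulate_counts(truth, 500, seed = 9)
  g2 <- bootstrap_lrt(cv, k_null = 1, n_boot = 19, seed = 10)
  expect_lte(g2$p_value, 0.05)
  expect_gt(g2$statistic, 10)
})
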