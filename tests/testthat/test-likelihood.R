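test_that("psi is the lapse-compressed cumulative Gaussian", {
  p <- psychometric_params(alpha = 1.3, beta = 0.7, lapse = 0.05)
  expect_equal(psi(1.3, p), 0.5)
  expect_equal(psi(1e6, p), 0.95)
  expect_equal(psi(-1e6, p), 0.05)
  p0 <- psychometric_params(alpha = 0, beta = 1, lapse = 0)
  expect_equal(psi(1, p0), pnorm(1))
  # bounded in [lapse, 1 - lapse]
  x <- seq(-50, 50, length.out = 101)
  expect_true(all(psi(x, p) >= 0.05 - 1e-12 & psi(x, p) <= 0.95 + 1e-12))
})

test_that("parameter containers validate their invariants", {
  expect_error(psychometric_params(0, beta = -1), "beta")
  expect_error(psychometric_params(0, 1, lapse = 0.7), "lapse")
  expect_error(psychometric_params(0, 1, eta = 1), "eta")
  expect_error(condition_counts("A", c(0, 0, 1), 10, c(1, 2, 3)), "unique")
  expect_error(condition_counts("A", c(0, 1), 10, c(11, 2)), "k <= n")
})

test_that("binomial log-likelihood matches direct product evaluation", {
  p <- psychometric_params(alpha = 0.5, beta = 0.4, lapse = 0.03)
  expect_equal(loglik_binomial(condition_counts("A", 0.5, 1, 1), p), log(0.5))
  set.seed(11)
  cc <- condition_counts("A", x = c(-3, -1, 0, 2, 4), n = c(5, 8, 10, 8, 5),
                         k = c(1, 3, 5, 6, 5))
  probs <- psi(cc$x, p)
  oracle <- log(prod(probs^cc$k * (1 - probs)^(cc$n - cc$k)))
  expect_equal(loglik_binomial(cc, p), oracle, tolerance = 1e-12)
  # boundary probabilities contradicted by counts give -Inf, not an error
  p_edge <- psychometric_params(alpha = 0, beta = 100, lapse = 0)
  cc_edge <- condition_counts("A", c(-5, 5), 10, c(5, 10))
  expect_identical(loglik_binomial(cc_edge, p_edge), -Inf)
})

test_that("betabinomial log-likelihood matches the beta-integral oracle", {
  # the spelled-out single cell: n=10, k=3, psi=0.5, eta=0.5 (eta' = 3)
  p_half <- psychometric_params(alpha = 0, beta = 1, lapse = 0.5, eta = 0.5)
  cc <- condition_counts("AV0", 0, 10, 3)
  expect_equal(loglik_betabinomial(cc, p_half),
               lbeta(4.5, 8.5) - lbeta(1.5, 1.5), tolerance = 1e-12)
  # random cells against numerical integration of the beta mixture
  set.seed(21)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    k <- sample(0:n, 1)
    psi_val <- runif(1, 0.05, 0.95)
    eta <- runif(1, 0.05, 0.6)
    params <- psychometric_params(alpha = 0, beta = 1,
                                  lapse = 0, eta = eta)
    # place the location so that psi(x) equals psi_val
    x <- qnorm(psi_val)
    got <- loglik_betabinomial(condition_counts("A", x, n, k), params)
    expect_equal(got, bb_cell_oracle(k, n, psi_val, eta), tolerance = 1e-8)
  }
})

test_that("betabinomial limits: eta -> 0 and single-trial cells", {
  cc <- condition_counts("A", x = seq(-4, 4, 2), n = 40,
                         k = c(3, 12, 20, 33, 39))
  p_small <- psychometric_params(0, 0.35, lapse = 0.02, eta = 1e-3)
  p_bin <- psychometric_params(0, 0.35, lapse = 0.02, eta = 0)
  expect_lt(abs(loglik_betabinomial(cc, p_small) - loglik_binomial(cc, p_bin)),
            1e-2)
  # a single Bernoulli draw carries no overdispersion information
  cc1 <- condition_counts("A", x = c(-1, 0.3, 2), n = 1, k = c(0, 1, 1))
  for (eta in c(0.1, 0.4, 0.8)) {
    p_eta <- psychometric_params(0, 0.8, lapse = 0.01, eta = eta)
    expect_equal(loglik_betabinomial(cc1, p_eta), loglik_binomial(cc1, p_eta),
                 tolerance = 1e-10)
  }
  expect_error(
    loglik_betabinomial(cc1, list(alpha = 0, beta = 1, lapse = 0, eta = 1)),
    "degenerate")
})

test_that("likelihood is invariant to translation and joint rescaling", {
  cc <- condition_counts("A", x = c(-4, -2, 0, 2, 4), n = 30,
                         k = c(2, 9, 16, 24, 28))
  params <- psychometric_params(alpha = 0.4, beta = 0.5, lapse = 0.02,
                                eta = 0.15)
  base <- loglik_betabinomial(cc, params)
  for (shift in c(-7, 1.3)) {
    cc_s <- condition_counts("A", cc$x + shift, cc$n, cc$k)
    p_s <- psychometric_params(params$alpha + shift, params$beta,
                               params$lapse, params$eta)
    expect_equal(loglik_betabinomial(cc_s, p_s), base, tolerance = 1e-10)
  }
  for (scale in c(0.25, 3)) {
    cc_s <- condition_counts("A", cc$x * scale, cc$n, cc$k)
    p_s <- psychometric_params(params$alpha * scale, params$beta / scale,
                               params$lapse, params$eta)
    expect_equal(loglik_betabinomial(cc_s, p_s), base, tolerance = 1e-10)
  }
})
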