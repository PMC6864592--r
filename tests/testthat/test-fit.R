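test_that("joint fit recovers parameters from noiseless expectation data", {
  obs <- fixture_observer(sigma = 3.5, lapse = 0.02, eta = 0)
  design <- make_design(5, 2000)
  counts <- noiseless_counts(obs, design)
  fit <- fit_joint(counts)
  jnd <- design$jnd_a
  expect_true(fit$converged)
  expect_true(all(abs(fit$alpha) < 0.05 * jnd))
  expect_equal(unname(fit$sigma[["A"]]), 3.5, tolerance = 0.05)
  expect_equal(unname(fit$sigma[["V"]]), 3.5, tolerance = 0.05)
  expect_equal(unname(fit$sigma[["AV"]]), 3.5 / sqrt(2), tolerance = 0.05)
  expect_equal(fit$lapse, 0.02, tolerance = 0.3)
  # slope/variance bookkeeping: sigma^2 = 0.5 * (1/beta)^2 for every condition
  expect_equal(unname(fit$sigma2[fit$slope_group]),
               unname(0.5 * (1 / fit$beta)^2), tolerance = 1e-12)
})

test_that("freeing the AV slopes on equal-slope data changes loglik little", {
  set.seed(31)
  obs <- fixture_observer(eta = 0.05)
  design <- make_design(5, 40)
  counts <- simulate_counts(obs, design)
  fit3 <- fit_joint(counts)
  fit5 <- fit_joint(counts, constraints = list(shared_av_slope = FALSE))
  expect_gte(fit5$loglik + 1e-6, fit3$loglik)  # nesting
  expect_lt(2 * (fit5$loglik - fit3$loglik), 9)  # ~ chi^2, 2 df
  expect_setequal(names(fit5$sigma), c("A", "V", "AV0", "AVp", "AVm"))
})

test_that("single-condition fit equals an independent coarse grid search", {
  set.seed(32)
  cc <- condition_counts("A", x = seq(-6, 6, 2), n = 25,
                         k = c(1, 4, 8, 14, 19, 22, 25))
  fit <- fit_conditions(list(cc), likelihood = "binomial")
  grid <- expand.grid(alpha = seq(-3, 3, length.out = 41),
                      beta = exp(seq(log(0.05), log(2), length.out = 41)),
                      lapse = seq(0, 0.09, length.out = 10))
  gl <- mapply(function(a, b, l) {
    loglik_binomial(cc, list(alpha = a, beta = b, lapse = l))
  }, grid$alpha, grid$beta, grid$lapse)
  expect_gte(fit$loglik, max(gl) - 0.1)
})

test_that("degenerate and incomplete inputs are rejected", {
  cc_flat <- condition_counts("V", x = c(-2, 0, 2), n = 10, k = c(0, 0, 0))
  expect_error(fit_conditions(list(cc_flat)), "V")
  obs <- fixture_observer()
  design <- make_design(5, 30)
  counts <- simulate_counts(obs, design)
  expect_error(fit_joint(counts[c("A", "V")]), "missing conditions")
})

test_that("saturated model nests the constrained fit and matches cell optima", {
  set.seed(33)
  obs <- fixture_observer(eta = 0.1)
  design <- make_design(4, 40)
  counts <- simulate_counts(obs, design)
  fit <- fit_joint(counts)
  sat <- fit_saturated(counts, eta_fixed = fit$eta)
  expect_gte(sat$loglik, fit$loglik)
  # binomial saturated optimum is exactly k/n
  sat0 <- fit_saturated(counts, eta_fixed = 0)
  kn <- unlist(lapply(counts, function(cc) cc$k / cc$n))
  expect_equal(sat0$p, unname(kn), tolerance = 1e-9)
  # betabinomial cell optima against a brute-force grid scan
  eta <- 0.3
  satb <- fit_saturated(counts["A"], eta_fixed = eta)
  etap <- 1 / eta^2 - 1
  cellll <- function(p, k, n) {
    lbeta(k + etap * p, n - k + etap * (1 - p)) -
      lbeta(etap * p, etap * (1 - p))
  }
  pgrid <- seq(1e-6, 1 - 1e-6, length.out = 100001)
  cc <- counts[["A"]]
  for (i in seq_along(cc$x)) {
    grid_best <- max(cellll(pgrid, cc$k[i], cc$n[i]))
    expect_equal(cellll(satb$p[i], cc$k[i], cc$n[i]), grid_best,
                 tolerance = 1e-6)
  }
})

test_that("compiled objective agrees with the R likelihood path", {
  set.seed(34)
  obs <- fixture_observer(eta = 0.12)
  design <- make_design(6, 40)
  counts <- simulate_counts(obs, design)
  fit <- fit_joint(counts)
  ll_r <- sum(vapply(seq_along(fit$counts), function(i) {
    loglik_betabinomial(fit$counts[[i]],
                        list(alpha = fit$alpha[[i]], beta = fit$beta[[i]],
                             lapse = fit$lapse, eta = fit$eta))
  }, numeric(1)))
  expect_equal(fit$loglik, ll_r, tolerance = 1e-8)
})
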