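test_that("design locations are JND-scaled, half-degree aligned and unique", {
  d2 <- make_design(2, 40)
  expect_equal(d2$probe_locations, c(-6, -5, -4, -3, -2, -1, 0, 1, 2, 3, 4, 5, 6))
  expect_equal(d2$disparity, 2)
  expect_equal(d2$n_per_cell, 40L)
  d1 <- make_design(1, 40)
  expect_equal(d1$probe_locations, seq(-3, 3, by = 0.5))
  # collision handling checked by brute force over awkward JNDs
  for (jnd in c(0.6, 0.3, 0.45, 0.8, 1.1, 2.3, 0.17)) {
    locs <- make_design(jnd)$probe_locations
    expect_length(unique(locs), 13)
    expect_equal(locs, sort(-locs))            # symmetric about zero
    expect_true(all(abs(locs * 2 - round(locs * 2)) < 1e-9))  # 0.5 deg grid
  }
  expect_error(make_design(0), "jnd_a")
})

test_that("p_right has the closed forms the 2IFC model implies", {
  obs_eq <- fixture_observer(sigma = 2, lapse = 0, eta = 0)
  for (cond in c("A", "V", "AV0", "AVp", "AVm"))
    expect_equal(p_right(obs_eq, cond, 0, disparity = 3), 0.5)
  # auditory condition at one auditory JND: Phi(1)
  obs <- observer_spec(sigma_a = 2, sigma_v = 1, lapse = 0, policy = "mle")
  expect_equal(p_right(obs, "A", 2 * sqrt(2)), pnorm(1), tolerance = 1e-12)
  # fused mean and variance for the mle policy
  w <- mle_weights(4, 1)
  s_av <- sqrt(mle_fused_variance(4, 1))
  x <- 1.7; d <- 2
  expect_equal(p_right(obs, "AVp", x, d),
               pnorm((w[["w_a"]] * (x - d / 2) + w[["w_v"]] * (x + d / 2)) /
                       (s_av * sqrt(2))), tolerance = 1e-12)
  # switching policy is the weight mixture of unisensory curves
  obs_sw <- observer_spec(2, 1, lapse = 0, policy = "switching")
  expect_equal(p_right(obs_sw, "AVm", x, d),
               w[["w_a"]] * pnorm((x + d / 2) / (2 * sqrt(2))) +
                 w[["w_v"]] * pnorm((x - d / 2) / (1 * sqrt(2))),
               tolerance = 1e-12)
  expect_error(p_right(obs, "AVX", 0), "unknown condition")
})

test_that("p_right is non-decreasing in x and lapse-bounded for any policy", {
  x <- seq(-20, 20, length.out = 81)
  observers <- list(
    fixture_observer(lapse = 0.04),
    observer_spec(4, 1.5, bias_a = 0.8, bias_v = -0.5, lapse = 0.1,
                  policy = "switching"),
    observer_spec(2, 3, lapse = 0, policy = "fixed_weight", w_a_fixed = 0.2))
  for (obs in observers) {
    for (cond in c("A", "V", "AV0", "AVp", "AVm")) {
      p <- p_right(obs, cond, x, disparity = 2.5)
      expect_true(all(diff(p) >= -1e-12))
      expect_true(all(p >= obs$lapse - 1e-12 & p <= 1 - obs$lapse + 1e-12))
    }
  }
})

test_that("cell_beta counts are exactly binomial when eta = 0", {
  obs <- fixture_observer(sigma = 3, lapse = 0.02, eta = 0)
  design <- make_design(4, 200)
  set.seed(41); counts <- simulate_counts(obs, design)
  set.seed(41)
  expected <- lapply(design$conditions, function(cond) {
    p <- p_right(obs, cond, design$probe_locations, design$disparity)
    rbinom(13, 200, p)
  })
  for (i in seq_along(counts))
    expect_equal(counts[[i]]$k, expected[[i]])
})

test_that("trialwise and cell_beta generators agree in their first moments", {
  obs <- fixture_observer(sigma = 3, lapse = 0.03, eta = 0)
  design <- make_design(4, 800)
  set.seed(42)
  k_beta <- simulate_counts(obs, design, "cell_beta")[["AV0"]]$k
  k_trial <- simulate_counts(obs, design, "trialwise")[["AV0"]]$k
  p_true <- p_right(obs, "AV0", design$probe_locations, design$disparity)
  se <- sqrt(p_true * (1 - p_true) / 800)
  expect_true(all(abs(k_beta / 800 - p_true) < 4 * se + 1e-3))
  expect_true(all(abs(k_trial / 800 - p_true) < 4 * se + 1e-3))
})

test_that("high-lapse observers respond near chance everywhere", {
  obs <- observer_spec(3, 3, lapse = 0.49, eta = 0)
  p <- p_right(obs, "A", c(-50, -5, 0, 5, 50))
  expect_true(all(p >= 0.49 & p <= 0.51))
})
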