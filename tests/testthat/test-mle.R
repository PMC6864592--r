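test_that("reliability weights and fused variance follow the closed forms", {
  expect_equal(mle_weights(2, 2), c(w_a = 0.5, w_v = 0.5))
  expect_equal(mle_weights(3, 1)[["w_v"]], 0.75)
  expect_equal(mle_fused_variance(2, 2), 1)
  expect_equal(mle_fused_variance(2, 1), 2 / 3)
  expect_error(mle_weights(-1, 2), "positive")
  expect_error(mle_fused_variance(0, 2), "positive")
  # weight normalization, monotonicity, and the fused-variance bound
  set.seed(61)
  s2a <- sort(runif(30, 0.1, 20)); s2v <- runif(30, 0.1, 20)
  w <- mapply(function(a, v) mle_weights(a, v)[["w_a"]], s2a, s2v[1])
  expect_true(all(diff(w) < 0))                      # decreasing in sigma2_a
  for (i in 1:30) {
    wi <- mle_weights(s2a[i], s2v[i])
    expect_equal(sum(wi), 1)
    expect_lt(mle_fused_variance(s2a[i], s2v[i]), min(s2a[i], s2v[i]))
  }
  # uninformative-cue limit
  expect_equal(mle_fused_variance(2, 1e12), 2, tolerance = 1e-6)
})

test_that("predicted conflict PSEs and the pooled weight are mutual inverses", {
  expect_equal(mle_predicted_pses(c(w_a = 0.5, w_v = 0.5), 2, 0.3),
               c(pse_avp = 0.3, pse_avm = 0.3))
  expect_equal(mle_predicted_pses(c(w_a = 1, w_v = 0), 2, 0)[["pse_avp"]], 1)
  expect_equal(mle_predicted_pses(c(w_a = 0.6, w_v = 0.4), 2, 0),
               c(pse_avp = 0.2, pse_avm = -0.2))
  # round trip over a sweep of weights, disparities and congruent biases
  for (w in seq(0, 1, by = 0.1)) {
    for (delta in c(0.5, 1, 3.7)) {
      for (c0 in c(-1.2, 0, 2)) {
        pses <- mle_predicted_pses(c(w_a = w, w_v = 1 - w), delta, c0)
        est <- empirical_weight_pooled(pses[["pse_avp"]], pses[["pse_avm"]],
                                       delta)
        expect_equal(est$w_a_emp, w, tolerance = 1e-12)
      }
    }
  }
})

test_that("pooled weight readout hits the capture limits without clamping", {
  expect_equal(empirical_weight_pooled(0.4, 0.4, 2)$w_a_emp, 0.5)
  expect_equal(empirical_weight_pooled(1, -1, 2)$w_a_emp, 1)
  expect_equal(empirical_weight_pooled(-1, 1, 2)$w_a_emp, 0)
  # overshoot is reported, not clamped
  expect_gt(empirical_weight_pooled(1.5, -1.5, 2)$w_a_emp, 1)
})

test_that("sided weight readout corrects for unisensory biases", {
  expect_equal(empirical_weight_sided(1, 0, 0, 2, "ALVR")$w_a_emp, 1)
  expect_equal(empirical_weight_sided(0, 0, 0, 2, "ALVR")$w_a_emp, 0.5)
  expect_equal(empirical_weight_sided(0.2, 0.3, -0.1, 2, "ALVR")$w_a_emp,
               1.3 / 2.4, tolerance = 1e-12)
  # VLAR mirror of the same configuration
  expect_equal(empirical_weight_sided(-0.2, -0.3, 0.1, 2, "VLAR")$w_a_emp,
               1.3 / 2.4, tolerance = 1e-12)
  # unbiased observers: sided and pooled readouts coincide
  pses <- mle_predicted_pses(c(w_a = 0.7, w_v = 0.3), 2, 0)
  expect_equal(empirical_weight_sided(pses[["pse_avp"]], 0, 0, 2,
                                      "ALVR")$w_a_emp, 0.7)
  expect_equal(empirical_weight_sided(pses[["pse_avm"]], 0, 0, 2,
                                      "VLAR")$w_a_emp, 0.7)
  expect_error(empirical_weight_sided(0, -1, 1, 2, "ALVR"), "degenerate")
})

test_that("fixed-weight observers are recovered end to end by the pooled readout", {
  set.seed(62)
  for (w_true in c(0.2, 0.5, 0.8)) {
    errs <- vapply(1:6, function(i) {
      obs <- fixture_observer(policy = "fixed_weight", w_a_fixed = w_true)
      est <- sim_fit_estimates(obs)
      est$w_a_emp - w_true
    }, numeric(1))
    expect_lt(abs(mean(errs)), 0.04)
  }
})
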