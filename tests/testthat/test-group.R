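test_that("paired one-sided test matches hand computation and Eq-style dz", {
  # differences {1, 1, 1, 2}: mean 1.25, sd 0.5, t = 5 on 3 df
  # the normality screen is bypassed (alpha 0): four tied differences are
  # legitimately flagged non-normal, but this case checks the t arithmetic
  x <- c(2, 3, 4, 6); y <- c(1, 2, 3, 4)
  rep <- paired_one_sided(x, y, "greater", alpha_normality = 0)
  expect_equal(rep$test_used, "paired_t_one_sided")
  expect_equal(rep$statistic, 5)
  expect_equal(rep$df, 3)
  expect_equal(rep$p, pt(5, 3, lower.tail = FALSE))
  expect_equal(rep$dz, 2.5)
  # dz equals the correlation-corrected standardized mean difference
  set.seed(91)
  a <- rnorm(20); b <- 0.6 * a + rnorm(20)
  rep2 <- paired_one_sided(a, b, "less")
  dz_formula <- abs(mean(a) - mean(b)) /
    sqrt(var(a) + var(b) - 2 * cor(a, b) * sd(a) * sd(b))
  expect_equal(rep2$dz, dz_formula, tolerance = 1e-12)
  expect_error(paired_one_sided(1:5, 1:5 + 1, "greater"), "degenerate")
  expect_error(paired_one_sided(1:2, 2:3, "greater"), "n >= 3")
})

test_that("normality screen routes heavy-tailed samples to the Wilcoxon", {
  set.seed(92)
  d_bad <- c(rnorm(30, 0.3, 0.05), 40, -35, 38, -32, 41, -39)
  x <- d_bad; y <- rep(0, length(x))
  expect_lt(lillie_test(d_bad)$p_value, 0.05)
  rep <- paired_one_sided(x, y, "greater")
  expect_equal(rep$test_used, "wilcoxon_one_sided")
  expect_true(is.na(rep$df))
  # clean normal data keep the t-test and the screen is deterministic
  set.seed(93); d_ok <- rnorm(30)
  expect_equal(lillie_test(d_ok)$p_value, lillie_test(d_ok)$p_value)
  expect_gt(lillie_test(d_ok)$p_value, 0.05)
  # the Monte-Carlo screen must not disturb the caller's RNG stream
  set.seed(94); r1 <- runif(1)
  set.seed(94); invisible(lillie_test(d_ok)); r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("one-sided JZS Bayes factor behaves and matches raw quadrature", {
  n <- 36
  # t = 0: evidence for the null
  d0 <- scale(rnorm(n), center = TRUE, scale = FALSE)[, 1]
  expect_gt(bf01_one_sided(d0, rep(0, n), "greater"), 3)
  # monotone decreasing in t for t > 0
  set.seed(95)
  base <- scale(rnorm(n))[, 1]
  bfs <- vapply(c(0.5, 1.5, 3, 5), function(shift) {
    bf01_one_sided(base + shift / sqrt(n), rep(0, n), "greater")
  }, numeric(1))
  expect_true(all(diff(bfs) < 0))
  expect_lt(bfs[4], 1 / 3)
  # dual-quadrature oracle at the n = 36, t = 0.33 fixture
  tstat <- 0.33
  d <- base * 1 + tstat / sqrt(n)   # unit variance, mean t/sqrt(n)
  got <- bf01_one_sided(d, rep(0, n), "greater")
  r <- sqrt(2) / 2
  grid <- seq(1e-6, 60, length.out = 400001)
  num <- sum(dt(tstat, n - 1, ncp = grid * sqrt(n)) *
               dcauchy(grid, 0, r)) * diff(grid[1:2]) / 0.5
  oracle <- dt(tstat, n - 1) / num
  expect_equal(got, oracle, tolerance = 0.01)
})

test_that("closed-form paired-t power is exact and monotone", {
  expect_equal(round(power_paired_t(0.58, 36, 0.05), 2), 0.96)
  expect_gt(power_paired_t(0.58, 5000, 0.05), 0.9999)
  # strictly increasing in both arguments on a grid
  grid_dz <- c(0.2, 0.5, 0.8); grid_n <- c(10, 25, 60)
  pw <- outer(grid_dz, grid_n, function(d, n)
    mapply(power_paired_t, d, n, MoreArgs = list(alpha = 0.05)))
  expect_true(all(apply(pw, 2, diff) > 0))
  expect_true(all(apply(pw, 1, diff) > 0))
  # Monte-Carlo oracle at dz = 0.5, n = 20
  set.seed(96)
  nmc <- 2e5
  m <- matrix(rnorm(nmc * 20, mean = 0.5), ncol = 20)
  tstats <- rowMeans(m) / (apply(m, 1, sd) / sqrt(20))
  mc <- mean(tstats > qt(0.95, 19))
  expect_lt(abs(power_paired_t(0.5, 20, 0.05) - mc), 0.005)
})

test_that("repeated-measures ANOVA matches aov and handles sphericity", {
  set.seed(97)
  vals <- matrix(rnorm(18, sd = 2), 6, 3) +
    matrix(rep(c(0, 0.5, 1.5), each = 6), 6, 3) + rnorm(6)
  got <- rm_anova_av_conditions(vals)
  df <- data.frame(y = as.vector(vals),
                   subj = factor(rep(1:6, 3)),
                   cond = factor(rep(1:3, each = 6)))
  a <- summary(stats::aov(y ~ cond + Error(subj / cond), data = df))
  tab <- a[["Error: subj:cond"]][[1]]
  rn <- trimws(rownames(tab))
  expect_equal(got$F, tab[rn == "cond", "F value"], tolerance = 1e-6)
  expect_equal(got$partial_eta2,
               tab[rn == "cond", "Sum Sq"] /
                 (tab[rn == "cond", "Sum Sq"] +
                    tab[rn == "Residuals", "Sum Sq"]),
               tolerance = 1e-8)
  # epsilon by the eigenvalue route of the double-centred covariance
  s <- cov(vals); k <- 3
  cmat <- diag(k) - 1 / k
  lam <- eigen(cmat %*% s %*% cmat, only.values = TRUE)$values
  lam <- lam[lam > 1e-12]
  expect_equal(got$epsilon, sum(lam)^2 / ((k - 1) * sum(lam^2)),
               tolerance = 1e-8)
  expect_equal(got$p, pf(got$F, got$df_corrected[1], got$df_corrected[2],
                         lower.tail = FALSE))
  # engineered exact compound symmetry: epsilon = 1, GG df = uncorrected df
  z <- qr.Q(qr(cbind(1, matrix(rnorm(8 * 3), 8, 3))))[, 2:4] * sqrt(7)
  vals_cs <- z %*% diag(c(1, 1, 1)) + rep(c(0, 1, 2), each = 8)
  got_cs <- rm_anova_av_conditions(vals_cs)
  expect_equal(got_cs$epsilon, 1, tolerance = 1e-8)
  expect_equal(got_cs$df_corrected, got_cs$df, tolerance = 1e-8)
  expect_error(rm_anova_av_conditions(vals[, 1:2]), "3 conditions")
  # identical triplets: no condition effect at all
  same <- matrix(rep(rnorm(6), 3), 6, 3)
  expect_equal(rm_anova_av_conditions(same)$F, 0)
})

test_that("two-sample report wraps the t-test with a pooled Cohen's d", {
  set.seed(98)
  g1 <- rnorm(15, 1); g2 <- rnorm(12, 0)
  rep <- two_sample_t(g1, g2, side = "two")
  sp <- sqrt((14 * var(g1) + 11 * var(g2)) / 25)
  expect_equal(rep$d, (mean(g1) - mean(g2)) / sp, tolerance = 1e-12)
  ht <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(rep$statistic, unname(ht$statistic))
  expect_equal(rep$p, ht$p.value)
  expect_equal(two_sample_t(g1, g1)$statistic, 0)
  expect_error(two_sample_t(rep(1, 5), rep(1, 5)), "degenerate")
})

test_that("weight-deviation power simulation is calibrated and monotone", {
  res0 <- simulate_power_weights(0, n_participants = 8, n_experiments = 25,
                                 n_per_cell = 15, seed = 3)
  se0 <- sqrt(0.05 * 0.95 / 25)
  expect_lt(res0$power, 0.05 + 3 * se0 + 0.05)
  res_mid <- simulate_power_weights(0.1, n_participants = 8,
                                    n_experiments = 25, n_per_cell = 15,
                                    seed = 3)
  res_big <- simulate_power_weights(0.25, n_participants = 8,
                                    n_experiments = 25, n_per_cell = 15,
                                    seed = 3)
  expect_gte(res_mid$power + 0.15, res0$power)     # MC slack
  expect_gte(res_big$power + 0.15, res_mid$power)
  expect_gt(res_big$power, 0.8)
  expect_error(simulate_power_weights(-0.1), "deviation")
})
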