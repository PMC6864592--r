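# Group-level inference battery: one-sided paired tests with a normality
# screen, effect sizes, one-sided Bayes factors, repeated-measures ANOVA,
# and closed-form plus simulation-based power analysis.

# Lilliefors-type Kolmogorov-Smirnov normality test (mean and SD estimated
# from the sample).  The null distribution of D is obtained by Monte Carlo
# with a fixed internal seed, so the screen is deterministic and does not
# disturb the caller's RNG stream.
lillie_d <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  pz <- stats::pnorm(z)
  i <- seq_len(n)
  max(i / n - pz, pz - (i - 1) / n)
}

#' Lilliefors-corrected Kolmogorov-Smirnov normality test
#'
#' @param x numeric sample (n >= 4).
#' @param n_mc Monte-Carlo replicates for the null distribution of D.
#' @return list with `statistic` (D) and `p_value`.
#' @export
lillie_test <- function(x, n_mc = 2000) {
  n <- length(x)
  if (n < 4) stop_invalid("need n >= 4 for the normality screen")
  d <- lillie_d(x)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(190237L)
  d_null <- vapply(seq_len(n_mc), function(i) lillie_d(stats::rnorm(n)),
                   numeric(1))
  list(statistic = d, p_value = (1 + sum(d_null >= d)) / (n_mc + 1))
}

#' One-sided paired comparison with normality screen
#'
#' Screens the paired differences for normality (Lilliefors-corrected KS at
#' alpha = .05); uses a one-sided paired t-test when the screen passes and a
#' one-sided Wilcoxon signed-rank test otherwise.  The effect size is
#' `dz = |mean(d)| / sd(d)`, i.e. the mean difference scaled by
#' `sqrt(sd_x^2 + sd_y^2 - 2*rho*sd_x*sd_y)`.
#'
#' @param x,y matched per-participant values.
#' @param direction alternative hypothesis for `x` relative to `y`
#'   (`"greater"` or `"less"`).
#' @param alpha_normality screening level (default .05).
#' @return A list of class `group_test_report`: `test_used`, `statistic`,
#'   `df`, `p`, `dz`, `normality_p`, `direction`, `n`.
#' @export
paired_one_sided <- function(x, y, direction = c("greater", "less"),
                             alpha_normality = 0.05) {
  direction <- match.arg(direction)
  if (length(x) != length(y)) stop_invalid("`x` and `y` lengths differ")
  n <- length(x)
  if (n < 3) stop_invalid("need n >= 3")
  d <- x - y
  if (stats::sd(d) == 0) stop_invalid("degenerate sample: zero-variance differences")
  # the KS screen needs n >= 4; tiny samples default to the t path
  normality_p <- if (n >= 4) lillie_test(d)$p_value else NA_real_
  if (!is.na(normality_p) && normality_p < alpha_normality) {
    ht <- stats::wilcox.test(x, y, paired = TRUE, alternative = direction,
                             exact = FALSE, correct = TRUE)
    test_used <- "wilcoxon_one_sided"
    df <- NA_real_
  } else {
    ht <- stats::t.test(x, y, paired = TRUE, alternative = direction)
    test_used <- "paired_t_one_sided"
    df <- unname(ht$parameter)
  }
  structure(list(test_used = test_used, statistic = unname(ht$statistic),
                 df = df, p = ht$p.value,
                 dz = abs(mean(d)) / stats::sd(d),
                 normality_p = normality_p, direction = direction, n = n),
            class = "group_test_report")
}

#' @export
print.group_test_report <- function(x, ...) {
  cat(sprintf("%s (n=%d, direction=%s): statistic=%.4f, df=%s, p=%.4g, dz=%.3f\n",
              x$test_used, x$n, x$direction, x$statistic,
              ifelse(is.na(x$df), "-", format(x$df)), x$p, x$dz))
  if (!is.na(x$normality_p))
    cat(sprintf("  normality screen p = %.3f\n", x$normality_p))
  invisible(x)
}

# Marginal likelihood of the t statistic under a Cauchy(0, r) effect-size
# prior truncated to the predicted sign, by adaptive quadrature.
jzs_marginal <- function(tstat, n, r, lower = 0, upper = Inf) {
  df <- n - 1
  f <- function(delta) {
    stats::dt(tstat, df, ncp = delta * sqrt(n)) * stats::dcauchy(delta, 0, r)
  }
  mass <- stats::pcauchy(upper, 0, r) - stats::pcauchy(lower, 0, r)
  out <- tryCatch(
    stats::integrate(f, lower, upper, rel.tol = 1e-9, abs.tol = 0),
    error = function(e) stop_invalid("Bayes factor integration failed: ",
                                     conditionMessage(e)))
  out$value / mass
}

#' One-sided JZS Bayes factor for a paired comparison
#'
#' Evidence for the point null (zero effect) against a one-sided alternative
#' with a Cauchy prior on positive standardized effect sizes (scale
#' `sqrt(2)/2`, mass restricted to the predicted direction) and the usual
#' Jeffreys prior on the variance.  `BF01 > 3` supports the null; `BF01 <
#' 1/3` supports the alternative.
#'
#' @inheritParams paired_one_sided
#' @param direction predicted direction of `x` relative to `y`.
#' @param r Cauchy prior scale (default `sqrt(2)/2`).
#' @return `BF01` (scalar).
#' @export
bf01_one_sided <- function(x, y, direction = c("greater", "less"),
                           r = sqrt(2) / 2) {
  direction <- match.arg(direction)
  d <- x - y
  if (direction == "less") d <- -d
  n <- length(d)
  if (n < 3) stop_invalid("need n >= 3")
  tstat <- mean(d) / (stats::sd(d) / sqrt(n))
  m1 <- jzs_marginal(tstat, n, r, lower = 0, upper = Inf)
  m0 <- stats::dt(tstat, n - 1)
  m0 / m1
}

#' Power of the one-sided paired t-test
#'
#' Exact noncentral-t computation: with effect size `dz` and `n` pairs the
#' noncentrality is `dz * sqrt(n)` on `n - 1` degrees of freedom.
#'
#' @param dz standardized effect size of the paired differences (> 0).
#' @param n number of pairs (>= 2).
#' @param alpha test level (default .05).
#' @param sides 1 (default) or 2.
#' @return Power (1 - beta).
#' @export
power_paired_t <- function(dz, n, alpha = 0.05, sides = 1) {
  if (dz <= 0) stop_invalid("`dz` must be > 0")
  if (n < 2) stop_invalid("`n` must be >= 2")
  df <- n - 1
  ncp <- dz * sqrt(n)
  if (sides == 1) {
    stats::pt(stats::qt(1 - alpha, df), df, ncp, lower.tail = FALSE)
  } else {
    crit <- stats::qt(1 - alpha / 2, df)
    stats::pt(crit, df, ncp, lower.tail = FALSE) +
      stats::pt(-crit, df, ncp, lower.tail = TRUE)
  }
}

#' Two-sample t-test report with Cohen's d
#'
#' @param x,y group samples (each n >= 2).
#' @param side `"two"`, `"greater"` or `"less"`.
#' @param var_equal pooled-variance t (default) or Welch.
#' @return list with `statistic`, `df`, `p`, `d` (Cohen's d, pooled SD).
#' @export
two_sample_t <- function(x, y, side = c("two", "greater", "less"),
                         var_equal = TRUE) {
  side <- match.arg(side)
  if (length(x) < 2 || length(y) < 2) stop_invalid("each group needs n >= 2")
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    stop_invalid("degenerate variance in both groups")
  alt <- switch(side, two = "two.sided", greater = "greater", less = "less")
  ht <- stats::t.test(x, y, alternative = alt, var.equal = var_equal)
  sp <- sqrt(((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
               (length(x) + length(y) - 2))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, d = (mean(x) - mean(y)) / sp, side = side)
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' For per-participant triplets of audiovisual noise estimates (congruent and
#' the two conflict conditions).  The Greenhouse-Geisser epsilon is computed
#' from the double-centred sample covariance of the repeated measures and
#' applied unconditionally to the degrees of freedom.
#'
#' @param values numeric matrix, participants x conditions (exactly 3
#'   columns).
#' @return list with `F`, `df` (uncorrected), `df_corrected`, `epsilon`, `p`
#'   (GG-corrected) and `partial_eta2`.
#' @export
rm_anova_av_conditions <- function(values) {
  values <- as.matrix(values)
  if (ncol(values) != 3) stop_invalid("expected exactly 3 conditions")
  if (nrow(values) < 3) stop_invalid("need >= 3 participants")
  if (anyNA(values)) stop_invalid("missing cells are not supported")
  n <- nrow(values); k <- ncol(values)
  grand <- mean(values)
  subj_means <- rowMeans(values)
  cond_means <- colMeans(values)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_tot <- sum((values - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  if (ss_cond < 1e-12 * max(1, ss_tot) && ss_err < 1e-12 * max(1, ss_tot)) {
    # no within-subject variability at all: no condition effect
    return(list(F = 0, df = c(df1, df2), df_corrected = c(df1, df2),
                epsilon = 1, p = 1, partial_eta2 = 0))
  }
  f_stat <- (ss_cond / df1) / (ss_err / df2)
  # Greenhouse-Geisser epsilon from the double-centred covariance
  s <- stats::cov(values)
  cmat <- diag(k) - matrix(1 / k, k, k)
  sdc <- cmat %*% s %*% cmat
  eps <- sum(diag(sdc))^2 / ((k - 1) * sum(sdc^2))
  df1c <- eps * df1; df2c <- eps * df2
  list(F = f_stat, df = c(df1, df2), df_corrected = c(df1c, df2c),
       epsilon = eps, p = stats::pf(f_stat, df1c, df2c, lower.tail = FALSE),
       partial_eta2 = ss_cond / (ss_cond + ss_err))
}

#' Simulation-based power for detecting a sensory-weight deviation
#'
#' Estimates the power of the group-level one-sided paired t-test to detect a
#' true deviation of the auditory weight below its reliability-weighted
#' prediction.  Each simulated experiment draws `n_participants` fixed-weight
#' observers with matched unisensory reliabilities (`w_a_mle = 0.5`) and
#' `w_a = 0.5 - deviation`, runs the full main design (by default 40 trials
#' at each of 13 JND-scaled probe locations per condition, disparity one
#' auditory JND), fits the constrained joint model, computes empirical
#' (pooled conflict-PSE) and predicted weights, and applies
#' [paired_one_sided()] at level `alpha`.
#'
#' @param deviation true weight deviation (>= 0).
#' @param n_participants participants per simulated experiment (default 36).
#' @param n_experiments simulated experiments (default 100).
#' @param alpha test level (default .05).
#' @param seed master seed.
#' @param jnd_a_mean,jnd_a_sdlog lognormal population distribution of the
#'   auditory JND across participants (deg).
#' @param lapse,eta generative lapse and overdispersion of every observer.
#' @param n_per_cell trials per (condition, location) cell (default 40).
#' @return list with `power` (rejection fraction), `n_experiments`,
#'   `rejected` (logical per experiment), `p_values`.
#' @export
simulate_power_weights <- function(deviation, n_participants = 36,
                                   n_experiments = 100, alpha = 0.05,
                                   seed = 1, jnd_a_mean = 5,
                                   jnd_a_sdlog = 0.2, lapse = 0.02,
                                   eta = 0.1, n_per_cell = 40) {
  if (deviation < 0) stop_invalid("`deviation` must be >= 0")
  set.seed(seed)
  exp_seeds <- sample.int(2^30, n_experiments)
  p_values <- numeric(n_experiments)
  for (e in seq_len(n_experiments)) {
    set.seed(exp_seeds[e])
    w_emp <- numeric(n_participants)
    w_mle <- numeric(n_participants)
    for (j in seq_len(n_participants)) {
      jnd <- stats::rlnorm(1, log(jnd_a_mean), jnd_a_sdlog)
      sigma <- jnd / sqrt(2)
      obs <- observer_spec(sigma_a = sigma, sigma_v = sigma,
                           lapse = lapse, eta = eta,
                           policy = "fixed_weight",
                           w_a_fixed = 0.5 - deviation)
      design <- make_design(jnd, n_per_cell)
      counts <- simulate_counts(obs, design, mode = "cell_beta")
      fit <- fit_joint(counts)
      est <- participant_estimates(fit, design$disparity)
      w_emp[j] <- est$w_a_emp
      w_mle[j] <- est$w_a_mle
    }
    rep <- paired_one_sided(w_mle, w_emp, direction = "greater")
    p_values[e] <- rep$p
  }
  rejected <- p_values < alpha
  list(power = mean(rejected), n_experiments = n_experiments,
       rejected = rejected, p_values = p_values, deviation = deviation)
}
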