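# Parametric bootstrap: goodness of fit against the saturated model,
# percentile confidence intervals, and within-subject parameter contrasts.

#' Parametric bootstrap of a joint psychometric fit
#'
#' For each replicate, a response probability is drawn per cell from a beta
#' distribution with mean equal to the fitted psychometric value and variance
#' `eta^2 * psi * (1 - psi)` (a plain binomial draw when `eta = 0`), counts
#' are drawn from a binomial, and the model is refit under identical
#' constraints (warm-started at the original solution).  Replicates whose
#' refit fails to converge are redrawn; more than 5% failures is an error.
#'
#' @param fit a converged `avfuse_fit`.
#' @param n_boot number of replicates (the study used 5000; tests use less).
#' @param seed integer seed; replicate b uses `seed + b`.
#' @param disparity optional audiovisual disparity; when supplied and the fit
#'   covers the five main conditions, derived columns (`w_a_emp`, `w_a_mle`,
#'   `sigma_av_mle`, ...) are added to each replicate.
#' @param max_fail_frac tolerated fraction of redrawn replicates.
#' @param tol simplex tolerance for the replicate refits.  The default 1e-7
#'   (one decade looser than the cold fit) changes replicate log-likelihoods
#'   by under 1e-5 while halving the refit cost.
#' @return A list of class `avfuse_boot`: `replicates` (data.frame, one row
#'   per replicate: all fitted parameters, the constrained and saturated
#'   log-likelihoods and the deviance), `n_redrawn`, `fit`, `observed`
#'   (same columns evaluated on the original fit), `n_boot`, `seed`.
#' @export
parametric_bootstrap <- function(fit, n_boot, seed = 1, disparity = NULL,
                                 max_fail_frac = 0.05, tol = 1e-7) {
  if (!isTRUE(fit$converged))
    stop_invalid("the original fit did not converge")
  if (n_boot < 1) stop_invalid("`n_boot` must be >= 1 (no replicates, no CIs)")
  fd <- fit$fit_data
  psi_hat <- fitted_psi(fit)
  eta <- fit$eta
  etap <- if (eta > 0) 1 / eta^2 - 1 else Inf
  betabin <- fit$likelihood == "betabinomial"
  cond_of_cell <- rep(seq_len(fd$ncond),
                      vapply(fd$counts, function(cc) length(cc$x), integer(1)))
  ncell <- length(psi_hat)
  jnd_guess <- stats::median(1 / fit$beta)
  step <- nm_steps(fd, jnd_guess, betabin, scale = 0.4)

  # draw one replicate's counts; a draw is usable if every condition keeps
  # mixed responses (the refit would be degenerate otherwise)
  draw_counts <- function(draw_id) {
    set.seed(seed + draw_id)
    p <- if (eta > 0) {
      stats::rbeta(ncell, etap * psi_hat, etap * (1 - psi_hat))
    } else psi_hat
    k <- stats::rbinom(ncell, fd$ns, p)
    tot <- rowsum(k, cond_of_cell)
    ntot <- rowsum(fd$ns, cond_of_cell)
    if (any(tot == 0 | tot == ntot)) NULL else k
  }

  n_redrawn <- 0L
  draw_id <- 0L
  kmat <- matrix(0, ncell, n_boot)
  par_mat <- matrix(0, length(fit$par), n_boot)
  loglik <- sat_loglik <- numeric(n_boot)
  pending <- seq_len(n_boot)
  while (length(pending)) {
    if (n_redrawn > max_fail_frac * n_boot + 2)
      stop_invalid("bootstrap instability: more than ",
                   round(100 * max_fail_frac), "% replicate refits failed")
    for (b in pending) {
      repeat {
        draw_id <- draw_id + 1L
        k <- draw_counts(draw_id)
        if (!is.null(k)) break
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > max_fail_frac * n_boot + 2)
          stop_invalid("bootstrap instability: more than ",
                       round(100 * max_fail_frac),
                       "% replicate refits failed")
      }
      kmat[, b] <- k
    }
    res <- boot_refit_cpp(kmat[, pending, drop = FALSE], fit$par, step,
                          fd$xs, fd$ns, fd$cond0, fd$slope_of_cond,
                          fd$ncond, fd$nslope, betabin, 20000L, tol)
    par_mat[, pending] <- res$par
    loglik[pending] <- res$loglik
    sat_loglik[pending] <- res$sat_loglik
    failed <- pending[!res$converged | !is.finite(res$loglik)]
    n_redrawn <- n_redrawn + length(failed)
    pending <- failed
  }
  replicates <- replicate_frame(par_mat, loglik, sat_loglik, fit, disparity)
  observed <- replicate_frame(
    matrix(fit$par, ncol = 1), fit$loglik,
    fit_saturated(fit$counts, eta_fixed = fit$eta)$loglik, fit, disparity)
  structure(list(replicates = replicates, observed = observed,
                 n_boot = n_boot, n_redrawn = n_redrawn, seed = seed,
                 fit = fit, disparity = disparity),
            class = "avfuse_boot")
}

# Vectorized construction of the replicate table from raw parameter columns.
replicate_frame <- function(par_mat, loglik, sat_loglik, fit, disparity) {
  fd <- fit$fit_data
  betabin <- fit$likelihood == "betabinomial"
  nc <- fd$ncond; nsl <- fd$nslope
  alphas <- t(par_mat[seq_len(nc), , drop = FALSE])
  colnames(alphas) <- paste0("alpha_", fd$conditions)
  betas <- exp(t(par_mat[nc + seq_len(nsl), , drop = FALSE]))
  sigmas <- 1 / (betas * sqrt(2))
  colnames(sigmas) <- paste0("sigma_", fd$slope_names)
  lapse <- vapply(par_mat[nc + nsl + 1, ], lapse_from_t, numeric(1))
  eta <- if (betabin) vapply(par_mat[nc + nsl + 2, ], eta_from_t, numeric(1))
    else rep(0, ncol(par_mat))
  out <- data.frame(alphas, sigmas, lapse = lapse, eta = eta,
                    loglik = loglik, sat_loglik = sat_loglik,
                    deviance = 2 * (sat_loglik - loglik))
  have_main <- all(AV_CONDITIONS %in% fd$conditions) && !is.null(disparity)
  if (have_main) {
    s2a <- out$sigma_A^2; s2v <- out$sigma_V^2
    out$w_a_mle <- (1 / s2a) / (1 / s2a + 1 / s2v)
    out$sigma_av_mle <- sqrt(s2a * s2v / (s2a + s2v))
    out$sigma_av_emp <- if (fit$shared_av_slope) out$sigma_AV else
      sqrt((out$sigma_AV0^2 + out$sigma_AVp^2 + out$sigma_AVm^2) / 3)
    out$w_a_emp <- (out$alpha_AVp - out$alpha_AVm) / (2 * abs(disparity)) + 0.5
    out$sigma_min_uni <- pmin(out$sigma_A, out$sigma_V)
  }
  out
}

fitted_psi <- function(fit) {
  fd <- fit$fit_data
  unlist(lapply(seq_along(fd$counts), function(i) {
    cc <- fd$counts[[i]]
    psi(cc$x, list(alpha = fit$alpha[[i]], beta = fit$beta[[i]],
                   lapse = fit$lapse))
  }), use.names = FALSE)
}

rebuild_counts <- function(fd, k_flat) {
  ncell <- vapply(fd$counts, function(cc) length(cc$x), integer(1))
  idx <- split(seq_along(k_flat), rep(seq_along(ncell), ncell))
  lapply(seq_along(fd$counts), function(i) {
    cc <- fd$counts[[i]]
    condition_counts(cc$condition, cc$x, cc$n, k_flat[idx[[i]]])
  })
}

#' Parametric-bootstrap goodness-of-fit test
#'
#' The statistic is the deviance `D = 2 * (loglik_saturated -
#' loglik_constrained)`; its null distribution is the replicate deviances,
#' and the p-value is the fraction of replicate deviances at least as large
#' as the observed one (equivalent to the tail of the likelihood ratio).
#' Insufficient fit is flagged at `p < .05`.
#'
#' @param boot an [parametric_bootstrap()] result.
#' @return A list of class `bootstrap_result` with `statistic_obs`,
#'   `null_distribution`, `p_value`, `insufficient_fit`.
#' @export
gof_test <- function(boot) {
  d_obs <- boot$observed$deviance
  d_rep <- boot$replicates$deviance
  p <- mean(d_rep >= d_obs)
  structure(list(statistic = "deviance", statistic_obs = d_obs,
                 null_distribution = d_rep, n_boot = boot$n_boot,
                 p_value = p, side = "one",
                 insufficient_fit = p < 0.05,
                 note = if (p == 0) sprintf("p < 1/%d", boot$n_boot)),
            class = "bootstrap_result")
}

#' Percentile confidence interval for a bootstrapped quantity
#'
#' @param boot an [parametric_bootstrap()] result.
#' @param quantity column name of `boot$replicates` (e.g. `"alpha_AV0"`,
#'   `"sigma_AV"`, `"w_a_emp"`).
#' @param level confidence level (default 0.95: the 2.5 and 97.5 percentiles).
#' @return Named vector `c(low, high)`.
#' @export
boot_ci <- function(boot, quantity, level = 0.95) {
  v <- boot$replicates[[quantity]]
  if (is.null(v)) stop_invalid("unknown replicate quantity '", quantity, "'")
  a <- (1 - level) / 2
  # order-statistic quantiles (type 1): exactly equivariant under monotone
  # transformations of the replicate set
  stats::setNames(stats::quantile(v, c(a, 1 - a), names = FALSE, type = 1),
                  c("low", "high"))
}

#' Within-subject bootstrap contrast test
#'
#' Tests a difference between two fitted or derived quantities within one
#' participant.  The null distribution is the bootstrapped differences
#' recentred at zero (replicate difference minus observed difference); the
#' one-sided p-value is the fraction of null values at least as large as the
#' observed difference, the two-sided version uses absolute values.  Order
#' the pair so the alternative hypothesis predicts `quantity1 > quantity2`.
#'
#' @param boot an [parametric_bootstrap()] result.
#' @param quantity1,quantity2 replicate column names.
#' @param side `"one"` or `"two"`.
#' @return A list of class `bootstrap_result` with the observed difference,
#'   the recentred null distribution, the percentile CI of the bootstrapped
#'   difference, and `p_value`.
#' @export
contrast_test <- function(boot, quantity1, quantity2, side = c("two", "one")) {
  side <- match.arg(side)
  q1 <- boot$replicates[[quantity1]]; q2 <- boot$replicates[[quantity2]]
  if (is.null(q1) || is.null(q2))
    stop_invalid("unknown replicate quantity")
  d_obs <- boot$observed[[quantity1]] - boot$observed[[quantity2]]
  d_b <- q1 - q2
  null <- d_b - d_obs
  p <- if (side == "one") mean(null >= d_obs) else mean(abs(null) >= abs(d_obs))
  a <- stats::quantile(d_b, c(0.025, 0.975), names = FALSE)
  structure(list(statistic = paste(quantity1, "-", quantity2),
                 statistic_obs = d_obs, null_distribution = null,
                 ci_low = a[1], ci_high = a[2], n_boot = boot$n_boot,
                 p_value = p, side = side),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("Bootstrap test:", x$statistic, "\n")
  cat(sprintf("  observed = %.4f, p = %.4g (%s-sided, %d replicates)\n",
              x$statistic_obs, x$p_value, x$side, x$n_boot))
  if (!is.null(x$ci_low))
    cat(sprintf("  95%% CI of bootstrapped difference: [%.4f, %.4f]\n",
                x$ci_low, x$ci_high))
  if (!is.null(x$insufficient_fit))
    cat("  insufficient fit:", x$insufficient_fit, "\n")
  invisible(x)
}
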