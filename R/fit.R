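# Constrained joint psychometric fitting.
#
# All conditions share one lapse rate and (betabinomial only) one
# overdispersion scale; every audiovisual condition shares one slope when
# `shared_av_slope = TRUE` (the primary fit: 5 PSEs, 3 slopes, lapse, eta);
# the control fit frees the three AV slopes (5 PSEs, 5 slopes).
# Optimization is multi-start Nelder-Mead on transformed parameters
# (log slope for positivity, logistic boxes for lapse [0, 0.1] and
# eta [1e-4, 0.999]) with the compiled objective in src/fit.cpp.

is_av_condition <- function(condition) startsWith(condition, "AV")

# Flatten a list of condition_counts into the arrays the C++ kernel expects.
fit_data <- function(counts_list, shared_av_slope = TRUE) {
  stopifnot(length(counts_list) >= 1)
  conditions <- vapply(counts_list, `[[`, character(1), "condition")
  names(counts_list) <- conditions
  if (anyDuplicated(conditions)) stop_invalid("duplicate condition labels")
  av <- is_av_condition(conditions)
  slope_group <- ifelse(av & shared_av_slope, "AV", conditions)
  slope_names <- unique(slope_group)
  xs <- unlist(lapply(counts_list, `[[`, "x"), use.names = FALSE)
  ks <- unlist(lapply(counts_list, `[[`, "k"), use.names = FALSE)
  ns <- unlist(lapply(counts_list, `[[`, "n"), use.names = FALSE)
  ncell <- vapply(counts_list, function(cc) length(cc$x), integer(1))
  cond0 <- rep(seq_along(conditions) - 1L, ncell)
  list(conditions = conditions, slope_group = slope_group,
       slope_names = slope_names,
       slope_of_cond = match(slope_group, slope_names) - 1L,
       xs = xs, ks = ks, ns = ns, cond0 = cond0,
       ncond = length(conditions), nslope = length(slope_names),
       counts = counts_list)
}

# Probit line fit of the response fractions: deterministic initial values.
init_alpha_beta <- function(cc) {
  f <- (cc$k + 0.5) / (cc$n + 1)
  z <- stats::qnorm(f)
  fit <- stats::lm.fit(cbind(1, cc$x), z)
  b <- fit$coefficients[2]
  span <- diff(range(cc$x))
  if (!is.finite(b) || b <= 0.05 / span) b <- 2 / span
  a <- -fit$coefficients[1] / b
  a <- min(max(a, min(cc$x)), max(cc$x))
  c(alpha = unname(a), beta = unname(b))
}

pack_par <- function(alphas, log_betas, lapse, eta, betabin) {
  par <- c(alphas, log_betas, t_from_lapse(lapse))
  if (betabin) par <- c(par, t_from_eta(eta))
  par
}

unpack_par <- function(par, fd, betabin) {
  nc <- fd$ncond; ns <- fd$nslope
  alphas <- stats::setNames(par[seq_len(nc)], fd$conditions)
  log_betas <- stats::setNames(par[nc + seq_len(ns)], fd$slope_names)
  lapse <- lapse_from_t(par[nc + ns + 1])
  eta <- if (betabin) eta_from_t(par[nc + ns + 2]) else 0
  list(alpha = alphas, log_beta = log_betas, lapse = lapse, eta = eta)
}

nm_steps <- function(fd, jnd_guess, betabin, scale = 1) {
  c(rep(0.25 * jnd_guess * scale, fd$ncond),
    rep(0.2 * scale, fd$nslope), 0.5 * scale, if (betabin) 0.5 * scale)
}

run_nm <- function(par, step, fd, betabin, maxit = 20000, tol = 1e-8) {
  nm_fit_cpp(par, step, fd$xs, fd$ks, fd$ns, fd$cond0, fd$slope_of_cond,
             fd$ncond, fd$nslope, betabin, maxit, tol)
}

#' Fit psychometric functions jointly across conditions
#'
#' Maximizes the summed betabinomial (or binomial) log-likelihood over one
#' PSE per condition, one slope per slope group, one shared lapse rate and
#' one shared overdispersion scale, using multi-start Nelder-Mead from a
#' deterministic grid of initializations (probit line fits, with the PSEs
#' additionally started at -1/0/+1 JND-guess offsets).  Sensory noise is
#' derived from each slope as `sigma^2 = 0.5 * (1/beta)^2`.
#'
#' @param counts_list list of [condition_counts()] (any subset of conditions;
#'   the main-experiment fit uses all five of A, V, AV0, AVp, AVm).
#' @param shared_av_slope share one slope across all AV conditions (the
#'   primary 3-slope fit)? `FALSE` gives the 5-slope control fit.
#' @param likelihood `"betabinomial"` (default) or `"binomial"`.
#' @param n_starts size of the deterministic start grid (default 3).
#' @param restart_budget maximum optimizer runs, including polish and
#'   fallback restarts (default 12).
#' @param tol Nelder-Mead absolute tolerance on the log-likelihood.
#' @param maxit maximum simplex iterations per start.
#' @return An object of class `avfuse_fit` with elements `alpha` (named PSEs),
#'   `beta` (named per-condition slopes), `sigma`/`sigma2` (named per slope
#'   group), `lapse`, `eta`, `loglik`, `converged`, `n_restarts_used`.
#' @export
fit_conditions <- function(counts_list, shared_av_slope = TRUE,
                           likelihood = c("betabinomial", "binomial"),
                           n_starts = 3, restart_budget = 12,
                           tol = 1e-8, maxit = 20000) {
  likelihood <- match.arg(likelihood)
  betabin <- likelihood == "betabinomial"
  fd <- fit_data(counts_list, shared_av_slope)
  for (cc in fd$counts) {
    tot <- sum(cc$k)
    if (tot == 0 || tot == sum(cc$n))
      stop_invalid("degenerate data: all responses identical in condition '",
                   cc$condition, "'")
  }
  ab <- vapply(fd$counts, init_alpha_beta, numeric(2))
  alphas0 <- ab["alpha", ]
  log_betas0 <- vapply(fd$slope_names, function(s) {
    mean(log(ab["beta", fd$slope_group == s]))
  }, numeric(1))
  jnd_guess <- 1 / exp(stats::median(log_betas0))

  offsets <- c(0, -1, 1, -0.5, 0.5, -2, 2)[seq_len(min(n_starts + 4, 7))]
  make_start <- function(i, beta_scale = 1) {
    pack_par(alphas0 + offsets[i] * jnd_guess, log_betas0 + log(beta_scale),
             lapse = 0.02, eta = 0.1, betabin)
  }

  runs <- list()
  for (i in seq_len(n_starts)) {
    runs[[length(runs) + 1L]] <-
      run_nm(make_start(i), nm_steps(fd, jnd_guess, betabin), fd, betabin,
             maxit, tol)
  }
  values <- vapply(runs, `[[`, numeric(1), "value")
  converged_pair <- function(v) {
    vs <- sort(v)
    length(vs) >= 2 && (vs[2] - vs[1]) <= 1e-3
  }
  # fall back to further grid points / slope rescalings when the best two
  # starts disagree, up to the restart budget
  extra <- 0L
  while (!converged_pair(values) && length(runs) < restart_budget) {
    extra <- extra + 1L
    idx <- min(n_starts + (extra + 1L) %/% 2L, length(offsets))
    scale <- if (extra %% 2L == 0L) 1.5 else 1 / 1.5
    runs[[length(runs) + 1L]] <-
      run_nm(make_start(idx, scale), nm_steps(fd, jnd_guess, betabin),
             fd, betabin, maxit, tol)
    values <- vapply(runs, `[[`, numeric(1), "value")
  }
  best <- runs[[which.min(values)]]
  # polish from the best point with a tight simplex
  if (length(runs) < restart_budget) {
    polish <- run_nm(best$par, nm_steps(fd, jnd_guess, betabin, scale = 0.05),
                     fd, betabin, maxit, tol)
    if (polish$value < best$value) best <- polish
    runs[[length(runs) + 1L]] <- polish
    values <- vapply(runs, `[[`, numeric(1), "value")
  }
  # converged: the two best runs agree in log-likelihood, and some run at
  # (numerically) the best value satisfied the simplex tolerance
  nm_ok <- vapply(runs, `[[`, logical(1), "converged")
  best_ok <- any(nm_ok & values <= min(values) + 1e-6)
  pars <- unpack_par(best$par, fd, betabin)
  beta_group <- exp(pars$log_beta)
  sigma2 <- 0.5 * (1 / beta_group)^2
  structure(list(
    conditions = fd$conditions,
    alpha = pars$alpha,
    beta = stats::setNames(beta_group[fd$slope_group], fd$conditions),
    slope_group = stats::setNames(fd$slope_group, fd$conditions),
    sigma = sqrt(sigma2), sigma2 = sigma2,
    lapse = pars$lapse, eta = if (betabin) pars$eta else 0,
    loglik = -best$value,
    converged = best_ok && converged_pair(values),
    n_restarts_used = length(runs),
    likelihood = likelihood, shared_av_slope = shared_av_slope,
    par = best$par, fit_data = fd, counts = fd$counts
  ), class = "avfuse_fit")
}

#' Joint fit of the five main-experiment conditions
#'
#' Convenience wrapper around [fit_conditions()] that checks all five
#' conditions (A, V, AV0, AVp, AVm) are present.
#'
#' @inheritParams fit_conditions
#' @param constraints list with logical element `shared_av_slope`.
#' @return An `avfuse_fit` object; see [fit_conditions()].
#' @export
fit_joint <- function(counts_list, constraints = list(shared_av_slope = TRUE),
                      likelihood = c("betabinomial", "binomial"), ...) {
  conditions <- vapply(counts_list, `[[`, character(1), "condition")
  missing <- setdiff(AV_CONDITIONS, conditions)
  if (length(missing))
    stop_invalid("missing conditions: ", paste(missing, collapse = ", "))
  fit_conditions(counts_list[match(AV_CONDITIONS, conditions)],
                 shared_av_slope = isTRUE(constraints$shared_av_slope),
                 likelihood = match.arg(likelihood), ...)
}

#' Saturated-model log-likelihood
#'
#' Models each (condition, location) cell with its own response probability,
#' maximizing the (beta)binomial cell likelihood by 1-D search with the
#' dispersion scale fixed (taken from the constrained fit).  By nesting, the
#' result is always at least the constrained fit's log-likelihood.
#'
#' @param counts_list list of [condition_counts()].
#' @param eta_fixed dispersion scale to hold fixed; `0` gives the plain
#'   binomial saturated model with cell optima `k/n`.
#' @return list with `loglik` (total) and `p` (per-cell optima, in the order
#'   the cells appear across `counts_list`).
#' @export
fit_saturated <- function(counts_list, eta_fixed = 0) {
  fd <- fit_data(counts_list, shared_av_slope = TRUE)
  out <- saturated_fit_cpp(fd$ks, fd$ns, eta_fixed)
  list(loglik = out$loglik, p = out$p)
}

# Single Nelder-Mead run warm-started from an existing solution; used by the
# parametric bootstrap where the refit starts near the truth.
refit_warm <- function(fit, counts_list, tol = 1e-8) {
  betabin <- fit$likelihood == "betabinomial"
  fd <- fit_data(counts_list, fit$shared_av_slope)
  jnd_guess <- stats::median(1 / fit$beta)
  res <- run_nm(fit$par, nm_steps(fd, jnd_guess, betabin, scale = 0.4),
                fd, betabin, maxit = 20000, tol = tol)
  pars <- unpack_par(res$par, fd, betabin)
  beta_group <- exp(pars$log_beta)
  sigma2 <- 0.5 * (1 / beta_group)^2
  structure(list(
    conditions = fd$conditions, alpha = pars$alpha,
    beta = stats::setNames(beta_group[fd$slope_group], fd$conditions),
    slope_group = stats::setNames(fd$slope_group, fd$conditions),
    sigma = sqrt(sigma2), sigma2 = sigma2,
    lapse = pars$lapse, eta = if (betabin) pars$eta else 0,
    loglik = -res$value, converged = isTRUE(res$converged),
    n_restarts_used = 1L, likelihood = fit$likelihood,
    shared_av_slope = fit$shared_av_slope,
    par = res$par, fit_data = fd, counts = fd$counts
  ), class = "avfuse_fit")
}

#' @export
print.avfuse_fit <- function(x, ...) {
  cat("Joint psychometric fit (", x$likelihood, ", ",
      if (x$shared_av_slope) "shared AV slope" else "free AV slopes",
      ")\n", sep = "")
  cat("  conditions:", paste(x$conditions, collapse = " "), "\n")
  cat("  PSE (deg):  ",
      paste(sprintf("%s=%.3f", names(x$alpha), x$alpha), collapse = " "), "\n")
  cat("  sigma (deg):",
      paste(sprintf("%s=%.3f", names(x$sigma), x$sigma), collapse = " "), "\n")
  cat(sprintf("  lapse=%.4f eta=%.4f loglik=%.3f converged=%s (restarts=%d)\n",
              x$lapse, x$eta, x$loglik, x$converged, x$n_restarts_used))
  invisible(x)
}
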