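#' Psychometric function parameters
#'
#' Container for the parameters of one cumulative-Gaussian psychometric
#' function: PSE `alpha` (deg), slope `beta` (1/deg), lapse rate `lapse` and
#' overdispersion scale `eta`.  The slope is the reciprocal of the just
#' noticeable difference (JND = 1/beta), and in a 2IFC task the sensory
#' variance follows from the slope as sigma^2 = 0.5 * (1/beta)^2, because the
#' noise of standard and probe both contribute to the discrimination.
#'
#' @param alpha PSE in degrees.
#' @param beta slope in 1/deg; must be positive.
#' @param lapse lapse rate in `[0, 0.5]`.
#' @param eta overdispersion scale in `[0, 1)`; `eta = 0` means plain
#'   binomial responding, larger values put beta-distributed trial-to-trial
#'   drift on the response probability.
#' @return A list of class `psychometric_params`.
#' @export
psychometric_params <- function(alpha, beta, lapse = 0, eta = 0) {
  if (!is.finite(beta) || beta <= 0) stop_invalid("`beta` must be positive")
  if (lapse < 0 || lapse > 0.5) stop_invalid("`lapse` must be in [0, 0.5]")
  if (eta < 0 || eta >= 1) stop_invalid("`eta` must be in [0, 1)")
  structure(list(alpha = alpha, beta = beta, lapse = lapse, eta = eta),
            class = "psychometric_params")
}

#' Per-condition response tallies
#'
#' One row of the design: for a single condition, the probe locations `x`,
#' the number of trials `n` and the number of "probe right" responses `k`
#' at each location.
#'
#' @param condition condition label (e.g. `"A"`, `"V"`, `"AV0"`, `"AVp"`,
#'   `"AVm"`).
#' @param x numeric vector of unique probe locations (deg).
#' @param n integer vector (or scalar) of trials per location.
#' @param k integer vector of "right" responses per location.
#' @return A list of class `condition_counts`.
#' @export
condition_counts <- function(condition, x, n, k) {
  n <- rep_len(as.numeric(n), length(x))
  k <- as.numeric(k)
  if (length(k) != length(x)) stop_invalid("`x` and `k` lengths differ")
  if (anyDuplicated(x)) stop_invalid("probe locations must be unique")
  if (any(k < 0 | k > n)) stop_invalid("need 0 <= k <= n at every location")
  structure(list(condition = as.character(condition), x = as.numeric(x),
                 n = n, k = k),
            class = "condition_counts")
}

#' Cumulative-Gaussian psychometric function with lapses
#'
#' `psi(x) = lapse + (1 - 2*lapse) * Phi(beta * (x - alpha))`, bounded in
#' `[lapse, 1 - lapse]`.
#'
#' @param x probe locations (deg).
#' @param params a [psychometric_params()] object (or any list with
#'   `alpha`, `beta`, `lapse`).
#' @return Probabilities of a "probe right" response.
#' @export
psi <- function(x, params) {
  params$lapse + (1 - 2 * params$lapse) *
    stats::pnorm(params$beta * (x - params$alpha))
}

#' Binomial log-likelihood of condition counts
#'
#' Sum over locations of `k*log(psi) + (n-k)*log(1-psi)`; the combinatorial
#' constant is omitted (it cancels in likelihood ratios and optimization).
#' A boundary probability that contradicts the counts yields `-Inf` rather
#' than an error.
#'
#' @param counts a [condition_counts()] object.
#' @param params a [psychometric_params()] object.
#' @return Log-likelihood (natural log).
#' @export
loglik_binomial <- function(counts, params) {
  p <- psi(counts$x, params)
  k <- counts$k; n <- counts$n
  term <- function(count, prob) {
    out <- numeric(length(count))
    pos <- count > 0
    out[pos] <- count[pos] * log(prob[pos]) # 0 * log(0) := 0
    out
  }
  sum(term(k, p) + term(n - k, 1 - p))
}

#' Betabinomial log-likelihood of condition counts
#'
#' The response probability in each cell is treated as beta-distributed with
#' mean `psi` and variance `eta^2 * psi * (1 - psi)`; with
#' `eta' = 1/eta^2 - 1` the marginal cell likelihood is
#' `B(k + eta'*psi, n - k + eta'*(1 - psi)) / B(eta'*psi, eta'*(1 - psi))`,
#' evaluated throughout via log-gamma.  `eta = 0` dispatches to
#' [loglik_binomial()]; `eta = 1` is degenerate and an error.
#'
#' @inheritParams loglik_binomial
#' @return Log-likelihood (natural log, combinatorial constant omitted).
#' @export
loglik_betabinomial <- function(counts, params) {
  eta <- params$eta %||% 0
  if (eta == 0) return(loglik_binomial(counts, params))
  if (eta >= 1) stop_invalid("`eta` = 1 is degenerate (eta' = 0)")
  etap <- 1 / eta^2 - 1
  p <- psi(counts$x, params)
  k <- counts$k; n <- counts$n
  ll <- numeric(length(p))
  inner <- p > 0 & p < 1
  ll[inner] <- lbeta(k[inner] + etap * p[inner],
                     n[inner] - k[inner] + etap * (1 - p[inner])) -
    lbeta(etap * p[inner], etap * (1 - p[inner]))
  # deterministic cells: consistent counts contribute 0, contradictions -Inf
  bad <- (!inner) & ((p == 0 & k > 0) | (p == 1 & k < n))
  ll[bad] <- -Inf
  sum(ll)
}
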