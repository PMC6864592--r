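# Model observers for the 2IFC audiovisual localization task.
#
# An observer is described by its unisensory noise SDs, localization biases,
# lapse rate, overdispersion scale, and an integration policy: `mle`
# (reliability-weighted fusion; variance follows the product-over-sum rule),
# `switching` (respond from one modality per trial, chosen with the MLE
# weights; no variance reduction) or `fixed_weight` (fusion with an imposed
# auditory weight).

#' Generative observer specification
#'
#' @param sigma_a auditory sensory noise SD (deg), > 0.
#' @param sigma_v visual sensory noise SD (deg), > 0.
#' @param bias_a,bias_v unisensory localization biases (deg); a positive bias
#'   shifts the PSE of that modality rightward.
#' @param lapse lapse rate in `[0, 0.5)`: with probability `2*lapse` the
#'   observer guesses uniformly, which compresses the psychometric asymptotes
#'   to `[lapse, 1 - lapse]`.
#' @param eta overdispersion scale in `[0, 1)` (beta-distributed drift of the
#'   per-cell response probability; used by the `cell_beta` generator).
#' @param policy `"mle"`, `"switching"` or `"fixed_weight"`.
#' @param w_a_fixed auditory weight in `[0, 1]`; required for
#'   `policy = "fixed_weight"`, ignored otherwise.
#' @param seed optional RNG seed recorded with the observer.
#' @return A list of class `observer_spec`.
#' @export
observer_spec <- function(sigma_a, sigma_v, bias_a = 0, bias_v = 0,
                          lapse = 0, eta = 0,
                          policy = c("mle", "switching", "fixed_weight"),
                          w_a_fixed = NULL, seed = NULL) {
  policy <- match.arg(policy)
  if (!is.finite(sigma_a) || sigma_a <= 0) stop_invalid("`sigma_a` must be > 0")
  if (!is.finite(sigma_v) || sigma_v <= 0) stop_invalid("`sigma_v` must be > 0")
  if (lapse < 0 || lapse >= 0.5) stop_invalid("`lapse` must be in [0, 0.5)")
  if (eta < 0 || eta >= 1) stop_invalid("`eta` must be in [0, 1)")
  if (policy == "fixed_weight") {
    if (is.null(w_a_fixed) || w_a_fixed < 0 || w_a_fixed > 1)
      stop_invalid("`w_a_fixed` must be in [0, 1] for policy 'fixed_weight'")
  }
  structure(list(sigma_a = sigma_a, sigma_v = sigma_v,
                 bias_a = bias_a, bias_v = bias_v,
                 lapse = lapse, eta = eta, policy = policy,
                 w_a_fixed = w_a_fixed, seed = seed),
            class = "observer_spec")
}

observer_weights <- function(observer) {
  if (observer$policy == "fixed_weight") {
    w_a <- observer$w_a_fixed
  } else {
    w_a <- mle_weights(observer$sigma_a^2, observer$sigma_v^2)[["w_a"]]
  }
  c(w_a = w_a, w_v = 1 - w_a)
}

#' Build the JND-scaled experimental design
#'
#' Probe locations are `(0, ±0.5, ±1, ±1.5, ±2, ±2.5, ±3) * jnd_a`, each
#' rounded to the nearest 0.5 deg; if rounding makes two locations collide,
#' the outer duplicate is pushed outward in 0.5 deg steps until all 13
#' locations are unique.  The audiovisual disparity is one auditory JND.
#'
#' @param jnd_a auditory just noticeable difference (deg), > 0.
#' @param n_per_cell trials per (condition, location) cell (default 40).
#' @return A list of class `experiment_design` with `probe_locations` (13
#'   signed degrees), `disparity`, `n_per_cell`, `conditions`, `jnd_a`.
#' @export
make_design <- function(jnd_a, n_per_cell = 40) {
  if (!is.finite(jnd_a) || jnd_a <= 0) stop_invalid("`jnd_a` must be > 0")
  if (n_per_cell <= 0) stop_invalid("`n_per_cell` must be > 0")
  round_half <- function(z) floor(z * 2 + 0.5) / 2
  mags <- round_half(seq(0, 3, by = 0.5) * jnd_a)
  for (i in seq_along(mags)[-1]) {
    while (mags[i] <= mags[i - 1]) mags[i] <- mags[i] + 0.5
  }
  locs <- sort(unique(c(-mags, mags)))
  stopifnot(length(locs) == 13)
  structure(list(probe_locations = locs, disparity = jnd_a,
                 n_per_cell = as.integer(n_per_cell),
                 conditions = AV_CONDITIONS, jnd_a = jnd_a),
            class = "experiment_design")
}

#' Expected probability of a "probe right" response
#'
#' Closed-form response probability for an observer at probe location `x`.
#' In a 2IFC comparison both intervals carry sensory noise, so the effective
#' discrimination SD is `sigma_eff * sqrt(2)` and the JND obeys
#' `JND^2 = 2 * sigma^2`.  For audiovisual conditions with signed disparity
#' `delta` the component locations are `x_v = x + delta/2` and
#' `x_a = x - delta/2`; fusion policies respond on the weighted combination,
#' the switching policy returns the weight-mixture of the two unisensory
#' psychometric functions.
#'
#' @param observer an [observer_spec()].
#' @param condition one of `"A"`, `"V"`, `"AV0"`, `"AVp"`, `"AVm"`.
#' @param x probe location(s), deg.
#' @param disparity signed audiovisual disparity (deg); by convention
#'   `AVp` uses `+disparity` and `AVm` uses `-disparity`.
#' @return Probability of responding "probe right".
#' @export
p_right <- function(observer, condition, x, disparity = 0) {
  if (!condition %in% AV_CONDITIONS)
    stop_invalid("unknown condition '", condition, "'")
  lam <- observer$lapse
  base <- function(mu, sigma_eff) stats::pnorm(mu / (sigma_eff * sqrt(2)))
  p0 <- switch(condition,
    A = base(x - observer$bias_a, observer$sigma_a),
    V = base(x - observer$bias_v, observer$sigma_v),
    {
      delta <- switch(condition, AV0 = 0, AVp = abs(disparity),
                      AVm = -abs(disparity))
      x_v <- x + delta / 2
      x_a <- x - delta / 2
      w <- observer_weights(observer)
      if (observer$policy == "switching") {
        w[["w_a"]] * base(x_a - observer$bias_a, observer$sigma_a) +
          w[["w_v"]] * base(x_v - observer$bias_v, observer$sigma_v)
      } else {
        mu <- w[["w_a"]] * (x_a - observer$bias_a) +
          w[["w_v"]] * (x_v - observer$bias_v)
        sigma_eff <- if (observer$policy == "mle") {
          sqrt(mle_fused_variance(observer$sigma_a^2, observer$sigma_v^2))
        } else {
          sqrt(w[["w_a"]]^2 * observer$sigma_a^2 +
                 w[["w_v"]]^2 * observer$sigma_v^2)
        }
        base(mu, sigma_eff)
      }
    })
  lam + (1 - 2 * lam) * p0
}

#' Simulate response counts for a full design
#'
#' `mode = "cell_beta"` draws, for each (condition, location) cell, a response
#' probability from a beta distribution with mean `p_right` and variance
#' `eta^2 * p * (1 - p)`, then counts from a binomial — exactly the data model
#' the betabinomial likelihood assumes.  `mode = "trialwise"` simulates every
#' trial: noisy internal estimates of standard and probe in each modality,
#' fused (or switched) per policy, response by sign comparison, with a
#' `2*lapse` probability of a uniform guess; `eta` is ignored trialwise.
#'
#' @param observer an [observer_spec()].
#' @param design an [make_design()] object.
#' @param mode `"cell_beta"` (default) or `"trialwise"`.
#' @return Named list of [condition_counts()], one per design condition.
#' @export
simulate_counts <- function(observer, design,
                            mode = c("cell_beta", "trialwise")) {
  mode <- match.arg(mode)
  xs <- design$probe_locations
  n <- design$n_per_cell
  out <- lapply(design$conditions, function(cond) {
    if (mode == "cell_beta") {
      p <- p_right(observer, cond, xs, design$disparity)
      eta <- observer$eta
      if (eta > 0) {
        feasible <- eta^2 * p * (1 - p) < p * (1 - p) | p %in% c(0, 1)
        if (any(!feasible))
          stop_invalid("infeasible beta variance in condition '", cond,
                       "' at x = ", xs[which(!feasible)[1]])
        etap <- 1 / eta^2 - 1
        pdraw <- ifelse(p %in% c(0, 1), p,
                        stats::rbeta(length(p), etap * p, etap * (1 - p)))
      } else {
        pdraw <- p
      }
      k <- stats::rbinom(length(xs), n, pdraw)
    } else {
      k <- vapply(xs, function(x) {
        sum(simulate_trials_cell(observer, cond, x, design$disparity, n))
      }, numeric(1))
    }
    condition_counts(cond, xs, n, k)
  })
  stats::setNames(out, design$conditions)
}

# One cell of trialwise simulation: returns a 0/1 response vector.
simulate_trials_cell <- function(observer, condition, x, disparity, n_trials) {
  draw <- function(mu, sigma) stats::rnorm(n_trials, mu, sigma)
  if (condition %in% c("A", "V")) {
    sigma <- if (condition == "A") observer$sigma_a else observer$sigma_v
    bias <- if (condition == "A") observer$bias_a else observer$bias_v
    probe <- draw(x - bias, sigma)
    standard <- draw(0, sigma)
  } else {
    delta <- switch(condition, AV0 = 0, AVp = abs(disparity),
                    AVm = -abs(disparity))
    a_probe <- draw(x - delta / 2 - observer$bias_a, observer$sigma_a)
    v_probe <- draw(x + delta / 2 - observer$bias_v, observer$sigma_v)
    a_std <- draw(0, observer$sigma_a)
    v_std <- draw(0, observer$sigma_v)
    w <- observer_weights(observer)
    if (observer$policy == "switching") {
      use_a <- stats::runif(n_trials) < w[["w_a"]]
      probe <- ifelse(use_a, a_probe, v_probe)
      standard <- ifelse(use_a, a_std, v_std)
    } else {
      probe <- w[["w_a"]] * a_probe + w[["w_v"]] * v_probe
      standard <- w[["w_a"]] * a_std + w[["w_v"]] * v_std
    }
  }
  resp <- as.integer(probe > standard)
  if (observer$lapse > 0) {
    guess <- stats::runif(n_trials) < 2 * observer$lapse
    resp[guess] <- as.integer(stats::runif(sum(guess)) < 0.5)
  }
  resp
}
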