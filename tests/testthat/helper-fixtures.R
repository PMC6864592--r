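# Shared fixtures: small deterministic datasets built in code.

# Matched-reliability observer of the stated world (lapse .02, eta .10).
fixture_observer <- function(sigma = 3.5, lapse = 0.02, eta = 0.1,
                             policy = "mle", ...) {
  observer_spec(sigma_a = sigma, sigma_v = sigma, lapse = lapse, eta = eta,
                policy = policy, ...)
}

# Deterministic counts from the noiseless psychometric expectation
# (k_i = round(n_i * psi_i)); exact self-consistency fixture.
noiseless_counts <- function(observer, design) {
  lapply(stats::setNames(nm = design$conditions), function(cond) {
    p <- p_right(observer, cond, design$probe_locations, design$disparity)
    condition_counts(cond, design$probe_locations, design$n_per_cell,
                     round(design$n_per_cell * p))
  })
}

# Independent oracle for one betabinomial cell log-likelihood via the
# rising-factorial product identity
#   B(k+a, n-k+b) / B(a, b) =
#     prod_{j<k}(a+j) * prod_{j<n-k}(b+j) / prod_{j<n}(a+b+j),
# evaluated in log space term by term -- a different route than the
# log-gamma evaluation used by the package (combinatorial constant omitted
# in both).
bb_cell_oracle <- function(k, n, psi, eta) {
  etap <- 1 / eta^2 - 1
  a <- etap * psi
  b <- etap * (1 - psi)
  up <- function(z, m) if (m < 1) 0 else sum(log(z + seq_len(m) - 1))
  up(a, k) + up(b, n - k) - up(a + b, n)
}

# Simulate, fit and extract estimates for one participant at the main design.
sim_fit_estimates <- function(observer, jnd = 5, n_per_cell = 40) {
  design <- make_design(jnd, n_per_cell)
  counts <- simulate_counts(observer, design)
  fit <- fit_joint(counts)
  participant_estimates(fit, design$disparity)
}
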