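---
title: "Audiovisual cue integration: models, fitting and inference in avfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Audiovisual cue integration: models, fitting and inference in avfuse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avfuse)
```

## The scientific problem

When an observer localizes an audiovisual event, the auditory and visual
systems each deliver a noisy spatial estimate. The ideal-observer
(maximum-likelihood, MLE) account of multisensory integration makes two
quantitative predictions. First, the fused estimate weights each modality by
its relative reliability (inverse variance),

$$\hat S_{AV} = w_A \hat S_A + w_V \hat S_V,\qquad
w_A = \frac{1/\sigma_A^2}{1/\sigma_A^2 + 1/\sigma_V^2},$$

and second, the fused variance is below either unisensory variance,

$$\sigma^2_{AV} = \frac{\sigma_A^2\,\sigma_V^2}{\sigma_A^2 + \sigma_V^2}
 < \min(\sigma_A^2, \sigma_V^2).$$

The variance prediction is the stringent one: a "cue-switching" observer who
responds from a single modality per trial (chosen with the same weights)
matches the weight prediction on average but shows no variance reduction.
`avfuse` implements the full analysis used to test these predictions in a
two-interval forced-choice (2IFC) spatial localization experiment: synthetic
data generation, constrained psychometric fitting, MLE predictions and
empirical weight readouts, parametric-bootstrap inference, and the
group-level test battery — all runnable without any data download.

## The psychometric model

Responses ("probe right" vs "probe left") at probe location $x$ follow

$$\psi(x) = \lambda + (1 - 2\lambda)\,\Phi\!\big(\beta\,(x - \alpha)\big),$$

with PSE $\alpha$ (deg), slope $\beta$ (1/deg) and lapse rate $\lambda$. In a
2IFC design both intervals carry sensory noise, so the just noticeable
difference relates to the sensory noise as $\mathrm{JND} = 1/\beta$ and
$\mathrm{JND}^2 = 2\sigma^2$; all reported $\sigma$ values use this
convention.

Because observers drift over hours of testing, the per-cell response
probability is modelled as beta-distributed with mean $\psi$ and variance
$\eta^2\,\psi(1-\psi)$; marginally the counts are betabinomial with
$\eta' = 1/\eta^2 - 1$:

$$L_i = \frac{B\!\big(k_i + \eta'\psi_i,\; n_i - k_i + \eta'(1-\psi_i)\big)}
             {B\!\big(\eta'\psi_i,\; \eta'(1-\psi_i)\big)}.$$

Combinatorial constants are omitted throughout (they cancel in ratios and
optimization). `eta = 0` reduces exactly to the binomial likelihood.

The main-experiment fit (`fit_joint()`) maximizes the summed log-likelihood
over the five conditions (A, V, AV congruent, AV $\pm$ conflict) under the
study's constraints: one PSE per condition, one slope for A, one for V, one
shared across the three AV conditions (the control fit frees them), and a
single lapse rate and a single overdispersion scale shared by all
conditions.

## Tunable parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `n_per_cell` | trials per (condition, location) cell | 40 | main-experiment cell count |
| `disparity` | audiovisual conflict | 1 auditory JND | maximizes weight-test power while keeping the conflict non-noticeable |
| `lapse` (generator) | stimulus-independent errors | 0.02 | typical for attentive observers; exclusion rejects $\lambda > .06$ |
| `eta` (generator) | overdispersion scale | 0.10 | mild non-stationarity (ICC $\approx$ .01) over long sessions |
| `jnd_a` population | auditory JND across simulated participants | lognormal, median 5 deg, sdlog 0.2 | plausible naive-listener spread for brief noise bursts |
| `bias_sd` | unisensory bias SD | 0.5 deg | small left/right biases as observed empirically |
| `blob_to_sigma` | visual noise per unit blob SD | 0.25 | the stimulus-to-noise mapping is empirical per participant; any monotone link exercises the staircase logic |
| `n_boot` | bootstrap replicates | 5000 (study), 500 in tests | percentile CIs and GOF tails |

## What the synthetic generator emulates — and what it does not

`simulate_counts()` has two modes. `cell_beta` draws each cell's response
probability from the beta law above and then binomial counts: it reproduces
*exactly* the statistical model the likelihood assumes, which makes it the
right generator for calibration checks. `trialwise` simulates every trial
mechanistically (noisy internal estimates for standard and probe, fusion or
switching, lapse as a $2\lambda$ uniform guess) and is the generator that
distinguishes fusion from switching; it carries no overdispersion.

A green test on synthetic data therefore establishes that the estimation and
inference machinery is correct and calibrated under the model's own
assumptions. It does not establish anything about real observers: session
drift with temporal structure, serial dependencies between trials,
asymmetric lapses, eye-movement artifacts and genuine causal-inference
behaviour are all outside the generator's world.

The full pipeline (`run_replication()`) also mimics the protocol around the
main experiment: session-1 auditory JND measurement on fixed then
individualized locations, six adaptive staircases (paired start values 2 and
40 deg; up/down rules U = 1, 2, 4 matched to the three target locations)
pooled by the quadratic mean over the last 20 reversals with the most
deviant track discarded, the visual confirmation series, "trials of no
interest" with variable blob size that are written to the trial tables but
never analysed, a 3% eye-tracking trial-exclusion surrogate, and the
pre/post exclusion screens (auditory accuracy $\ge 90\%$ at $\pm 10$ deg,
predicted fused-variance reduction of at least one third, $\lambda \le .06$,
goodness of fit $p \ge .05$) with replacement until the target cohort size.

## Numerical choices

* **Optimization.** Multi-start Nelder-Mead on transformed parameters:
  $\log\beta$ for positivity, logistic boxes for $\lambda \in [0, 0.1]$ and
  $\eta \in [10^{-4}, 0.999]$. The lapse cap at 0.1 is intentional: the
  exclusion screen already rejects $\lambda > .06$, and capping prevents
  slope/lapse trade-offs. Starts come from probit line fits with the PSEs
  additionally offset by $\{-1, 0, +1\}$ JND-guesses; restart budget 12; a
  fit is `converged` only when its two best runs agree within $10^{-3}$
  log-likelihood units.
* **Boundary plateaus.** The logistic transforms saturate beyond $|t| = 7$,
  making box boundaries exactly flat. Without this the simplex crawls down a
  vanishing gradient whenever the optimum sits on a boundary (typically
  $\hat\eta \to 0$), and the run stalls. The sacrificed resolution (logistic
  tails below $10^{-3}$) is far inside the likelihood's flat region.
* **Stall restarts.** A long simplex run can degenerate; when the function
  spread stops shrinking geometrically the optimizer restarts from the
  incumbent with a fresh simplex (up to four rounds).
* **Bootstrap refits** warm-start at the original solution and use a simplex
  tolerance of $10^{-7}$ instead of $10^{-8}$; this changes replicate
  log-likelihoods by under $10^{-5}$ (far below any statistic's resolution)
  while halving the cost of the $10^5$-refit calibration runs. Replicates
  whose refit fails to converge, or whose drawn data are degenerate
  (a condition with all-identical responses), are redrawn and counted;
  more than 5% redraws aborts with an error.
* **Saturated model.** One response probability per cell at the constrained
  fit's $\hat\eta$, each maximized by golden-section search; the binomial
  case uses the exact optimum $k/n$. The goodness-of-fit statistic is the
  deviance $D = 2(\ell_{\mathrm{sat}} - \ell_{\mathrm{con}})$ with a
  $\ge$ tail over replicate deviances — the numerically stable equivalent of
  the likelihood-ratio orientation.
* **Percentile CIs** use order-statistic (type 1) quantiles, which are
  exactly equivariant under monotone reparameterization ($\sigma$ vs
  $\sigma^2$).
* **Ties and degenerate inputs.** Equal-likelihood restarts resolve to the
  first found; a condition with all-identical responses raises a
  degenerate-data error naming the condition; zero-variance paired
  differences raise an error rather than returning $t = 0$ (the latter wins
  over the convention that identical samples give $p = 0.5$).

## Design choices where the design was open

* **Staircase steps** are multiplicative (additive on $\log\sigma_{blob}$)
  with a 5% base down-step, bounded in $[0.1, 60]$ deg; only the starting
  values and the step-ratio rule
  $f = (\Delta^-/(\Delta^- + \Delta^+))^{1/U}$ are fixed by the protocol.
  The pooling formula is read as the quadratic mean (RMS) of reversal
  values, which is the only reading consistent with pooling "across
  $\sigma^2$".
* **Empirical weights are never clamped** to $[0,1]$: clamping would bias
  the group comparison toward the null.
* **The predicted conflict PSEs anchor at the congruent-AV PSE**, which
  makes prediction and pooled readout exact mutual inverses and reproduces
  the standard bias handling.
* **Overdispersion is fitted jointly** with the other parameters (not
  profiled), and the saturated model reuses the constrained $\hat\eta$ per
  replicate so both likelihoods share a dispersion scale; a binomial-GOF
  variant is available via `likelihood = "binomial"`.
* **The Bayes factor** is the one-sided JZS paired-sample
  $\mathrm{BF}_{01}$: Cauchy prior (scale $\sqrt{2}/2$) on standardized
  effect sizes truncated to the predicted direction, integrated by adaptive
  quadrature and renormalized by the truncation mass. Thresholds 3 and 1/3
  are reported, not enforced.
* **The normality screen** is a Lilliefors-corrected one-sample KS test on
  the paired differences, with a fixed-seed Monte-Carlo null (2000 draws) so
  the screen is deterministic and leaves the caller's RNG stream untouched.
* **Greenhouse-Geisser correction** is applied unconditionally in the
  repeated-measures ANOVA (no sphericity gate), with $\hat\varepsilon$ from
  the double-centred covariance of the repeated measures.
* **Power-simulation defaults**: the appendix-style weight-deviation power
  analysis draws fixed-weight observers at $w_A = 0.5 - \delta$ with matched
  reliabilities, lapse .02 and $\eta = .10$; the protocol source does not
  state its generative settings, so these mirror the package's stated world
  and are exposed as arguments.

## Known limitations

* The goodness-of-fit parametric bootstrap inherits the small-sample
  downward bias of the maximum-likelihood overdispersion estimate: when the
  generative $\eta$ is clearly positive but weakly identified (65 cells of
  40 trials), $\hat\eta$ piles up near zero in a sizable fraction of fits
  and the deviance tail is then slightly anticonservative. The calibration
  tests quantify this at the stated world; it is a property of the method
  being reproduced, not of this implementation.
* The visual stimulus-size-to-noise link is a stand-in
  ($\sigma_V = c\,\sigma_{blob}$); only its monotonicity matters for the
  staircase logic.
* `trialwise` simulation has no overdispersion mechanism, and `cell_beta`
  has no trial-level fusion mechanism; the two agree in their first two
  moments only as $\eta \to 0$.
* Reading real deposited trial tables is supported only through the
  column-mapped CSV schema; no attempt is made to parse any native format.
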