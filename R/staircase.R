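# Transformed weighted up/down staircases on the visual blob size.
#
# The blob SD (sigma_blob) is decreased (easier) after each incorrect
# response and increased (harder) after U consecutive correct responses.
# With up/down log-step sizes d_up/d_down the track converges where
# fraction_correct = (d_down / (d_down + d_up))^(1/U).  Steps are
# multiplicative (additive on log sigma_blob): the paper-level description
# fixes only the starting values and the step-ratio rule, so the base step
# is a package choice (down-step 5% of the current level), bounded in
# [0.1, 60] deg.

#' Convergence target of a weighted up/down rule
#'
#' @param step_up,step_down up/down step sizes (log units).
#' @param u consecutive-correct rule parameter.
#' @return The fraction correct at which the track is stationary:
#'   `(step_down / (step_down + step_up))^(1/u)`.
#' @export
staircase_target <- function(step_up, step_down, u) {
  (step_down / (step_down + step_up))^(1 / u)
}

#' Step ratio achieving a target convergence fraction
#'
#' Inverts the weighted up/down rule: `step_up / step_down =
#' (1 - f^u) / f^u` for target fraction `f`.
#'
#' @param target_fraction intended convergence probability.
#' @param u consecutive-correct rule parameter.
#' @return The ratio `step_up / step_down`.
#' @export
staircase_step_ratio <- function(target_fraction, u) {
  fu <- target_fraction^u
  (1 - fu) / fu
}

#' Initialize an adaptive staircase
#'
#' @param sigma_blob starting blob SD (deg); the study used 2 and 40 deg
#'   tracks.
#' @param u number of consecutive correct responses required before the
#'   stimulus is made harder (1, 2 or 4 in the study).
#' @param target_fraction intended convergence probability; sets the
#'   up/down step ratio via [staircase_step_ratio()].
#' @param step_down downward (easier) step in log units (default
#'   `log(1/0.95)`, i.e. a 5% multiplicative decrease).
#' @param bounds lower/upper clamp on sigma_blob (deg).
#' @return A list of class `staircase_state`.
#' @export
staircase_state <- function(sigma_blob, u = 1, target_fraction = 0.5,
                            step_down = log(1 / 0.95),
                            bounds = c(0.1, 60)) {
  if (!u %in% c(1, 2, 4)) stop_invalid("`u` must be 1, 2 or 4")
  if (sigma_blob <= 0) stop_invalid("`sigma_blob` must be > 0")
  structure(list(
    sigma_blob = sigma_blob, u = u,
    step_down = step_down,
    step_up = step_down * staircase_step_ratio(target_fraction, u),
    target_fraction = target_fraction,
    bounds = bounds, streak = 0L, last_move = 0L,
    reversals = numeric(0), reversal_trials = integer(0),
    trial_correct = logical(0)
  ), class = "staircase_state")
}

#' Advance a staircase by one response
#'
#' Incorrect responses decrease sigma_blob immediately and reset the
#' consecutive-correct counter; every `u`-th consecutive correct response
#' increases it.  A change of movement direction records the pre-move
#' sigma_blob as a reversal value.  The level is clamped to the state's
#' bounds, so underflow cannot occur.
#'
#' @param state a [staircase_state()].
#' @param correct logical: was the response correct?
#' @return The updated `staircase_state`.
#' @export
staircase_step <- function(state, correct) {
  state$trial_correct <- c(state$trial_correct, isTRUE(correct))
  move <- 0L
  if (correct) {
    state$streak <- state$streak + 1L
    if (state$streak >= state$u) {
      move <- 1L
      state$streak <- 0L
    }
  } else {
    move <- -1L
    state$streak <- 0L
  }
  if (move != 0L) {
    if (state$last_move != 0L && move != state$last_move) {
      state$reversals <- c(state$reversals, state$sigma_blob)
      state$reversal_trials <- c(state$reversal_trials,
                                 length(state$trial_correct))
    }
    log_s <- log(state$sigma_blob) +
      if (move > 0L) state$step_up else -state$step_down
    state$sigma_blob <- min(max(exp(log_s), state$bounds[1]), state$bounds[2])
    state$last_move <- move
  }
  state
}

#' Pool six staircases into one blob-size estimate
#'
#' Each staircase contributes the quadratic mean (RMS) of its last 20
#' reversal values.  The staircase whose estimate lies farthest from the
#' six-track pooled RMS is discarded as a potential outlier, and the final
#' estimate is the RMS over the remaining 5 x 20 reversal values.
#'
#' @param staircases list of six [staircase_state()] objects, each with at
#'   least 30 reversals.
#' @param n_last reversals per staircase entering the estimate (default 20).
#' @return Final pooled sigma_blob (deg).
#' @export
pool_staircases <- function(staircases, n_last = 20) {
  if (length(staircases) != 6) stop_invalid("expected 6 staircases")
  rms <- function(v) sqrt(mean(v^2))
  lasts <- lapply(staircases, function(s) {
    if (length(s$reversals) < 30)
      stop_invalid("insufficient data: a staircase has fewer than 30 reversals")
    utils::tail(s$reversals, n_last)
  })
  per_track <- vapply(lasts, rms, numeric(1))
  pooled_all <- rms(unlist(lasts))
  drop <- which.max(abs(per_track - pooled_all))
  rms(unlist(lasts[-drop]))
}

#' Run a staircase against a simulated observer
#'
#' Drives [staircase_step()] with Bernoulli responses whose accuracy is given
#' by `p_correct(sigma_blob)` until the requested number of reversals is
#' reached.
#'
#' @param state a [staircase_state()].
#' @param p_correct function of sigma_blob returning P(correct).
#' @param n_reversals stop after this many reversals (default 30, as in the
#'   adaptive phase of the study).
#' @param max_trials safety cap.
#' @return The final `staircase_state`.
#' @export
run_staircase <- function(state, p_correct, n_reversals = 30,
                          max_trials = 4000) {
  trials <- 0L
  while (length(state$reversals) < n_reversals && trials < max_trials) {
    trials <- trials + 1L
    correct <- stats::runif(1) < p_correct(state$sigma_blob)
    state <- staircase_step(state, correct)
  }
  state
}
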