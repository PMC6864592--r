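# Maximum-likelihood cue-integration predictions and empirical weights.
#
# From the unisensory variances the ideal observer weights each cue by its
# relative reliability (inverse variance) and attains a fused variance equal
# to the product over the sum of the unisensory variances.  Empirical weights
# are read out from the PSE shifts induced by small audiovisual conflicts;
# they are deliberately not clamped to [0, 1], since sampling noise can push
# estimates outside and clamping would bias group tests toward the null.

#' Reliability-weighted cue weights
#'
#' @param sigma2_a auditory variance (deg^2), > 0.
#' @param sigma2_v visual variance (deg^2), > 0.
#' @return Named vector `c(w_a, w_v)` with `w_a + w_v = 1`.
#' @export
mle_weights <- function(sigma2_a, sigma2_v) {
  if (any(!is.finite(c(sigma2_a, sigma2_v))) || sigma2_a <= 0 || sigma2_v <= 0)
    stop_invalid("variances must be positive")
  w_a <- (1 / sigma2_a) / (1 / sigma2_a + 1 / sigma2_v)
  c(w_a = w_a, w_v = 1 - w_a)
}

#' Predicted variance of the fused audiovisual estimate
#'
#' Product over sum of the unisensory variances; strictly below the smaller
#' of the two inputs.
#'
#' @inheritParams mle_weights
#' @return Fused variance (deg^2).
#' @export
mle_fused_variance <- function(sigma2_a, sigma2_v) {
  if (any(!is.finite(c(sigma2_a, sigma2_v))) || sigma2_a <= 0 || sigma2_v <= 0)
    stop_invalid("variances must be positive")
  sigma2_a * sigma2_v / (sigma2_a + sigma2_v)
}

#' Predicted PSEs of the conflict conditions
#'
#' With the visual component moved by `+disparity/2` and the auditory by
#' `-disparity/2` (and vice versa for the negative-disparity condition), the
#' fused percept shifts by `(w_a - w_v) * disparity / 2` relative to the
#' congruent PSE, which anchors the prediction (the congruent, A and V biases
#' are assumed equal).
#'
#' @param weights named vector from [mle_weights()] (or any `c(w_a, w_v)`).
#' @param disparity audiovisual disparity magnitude (deg), > 0.
#' @param pse_congruent fitted PSE of the congruent audiovisual condition.
#' @return Named vector `c(pse_avp, pse_avm)`.
#' @export
mle_predicted_pses <- function(weights, disparity, pse_congruent = 0) {
  if (disparity <= 0) stop_invalid("`disparity` must be > 0")
  shift <- (weights[["w_a"]] - weights[["w_v"]]) * disparity / 2
  c(pse_avp = pse_congruent + shift, pse_avm = pse_congruent - shift)
}

#' Full MLE prediction from unisensory fits
#'
#' @inheritParams mle_weights
#' @param disparity audiovisual disparity magnitude (deg).
#' @param pse_congruent congruent-condition PSE anchoring the predicted
#'   conflict PSEs.
#' @return A list of class `mle_prediction` with `w_a_mle`, `w_v_mle`,
#'   `sigma2_av_mle`, `pse_avp_mle`, `pse_avm_mle`.
#' @export
mle_prediction <- function(sigma2_a, sigma2_v, disparity, pse_congruent = 0) {
  w <- mle_weights(sigma2_a, sigma2_v)
  pses <- mle_predicted_pses(w, disparity, pse_congruent)
  structure(list(w_a_mle = w[["w_a"]], w_v_mle = w[["w_v"]],
                 sigma2_av_mle = mle_fused_variance(sigma2_a, sigma2_v),
                 pse_avp_mle = pses[["pse_avp"]],
                 pse_avm_mle = pses[["pse_avm"]]),
            class = "mle_prediction")
}

#' Empirical auditory weight from the pooled conflict PSEs
#'
#' `w_a = (PSE_avp - PSE_avm) / (2 * disparity) + 1/2`.  Assumes the
#' congruent, auditory and visual PSEs coincide; exact inverse of
#' [mle_predicted_pses()] under that assumption.  Not clamped to `[0, 1]`.
#'
#' @param pse_avp,pse_avm fitted PSEs of the positive/negative disparity
#'   conditions (deg).
#' @param disparity audiovisual disparity magnitude (deg), > 0.
#' @return A list of class `weight_estimate` with `w_a_emp`, `variant`
#'   (`"pooled"`), and the inputs used.
#' @export
empirical_weight_pooled <- function(pse_avp, pse_avm, disparity) {
  if (disparity <= 0) stop_invalid("`disparity` must be > 0")
  w <- (pse_avp - pse_avm) / (2 * abs(disparity)) + 0.5
  structure(list(w_a_emp = w, variant = "pooled",
                 inputs_used = list(pse_avp = pse_avp, pse_avm = pse_avm,
                                    disparity = disparity)),
            class = "weight_estimate")
}

#' Empirical auditory weight from a single conflict condition
#'
#' Bias-corrected readout using the unisensory PSEs as capture anchors.  For
#' the auditory-left/visual-right condition (`side = "ALVR"`, disparity +X):
#' `w_a = (PSE_av - (PSE_v - X/2)) / ((PSE_a + X/2) - (PSE_v - X/2))`;
#' the visual-left/auditory-right condition mirrors the signs.
#'
#' @param pse_av_conflict fitted PSE of the conflict condition (deg).
#' @param pse_a,pse_v fitted unisensory PSEs (deg).
#' @param x disparity magnitude X (deg), > 0.
#' @param side `"ALVR"` (disparity +X) or `"VLAR"` (disparity -X).
#' @return A list of class `weight_estimate` with `w_a_emp` and `variant`
#'   equal to `side`.
#' @export
empirical_weight_sided <- function(pse_av_conflict, pse_a, pse_v, x,
                                   side = c("ALVR", "VLAR")) {
  side <- match.arg(side)
  if (x <= 0) stop_invalid("`x` must be > 0")
  s <- if (side == "ALVR") 1 else -1
  cap_a <- pse_a + s * x / 2   # pure auditory capture PSE
  cap_v <- pse_v - s * x / 2   # pure visual capture PSE
  denom <- cap_a - cap_v
  if (abs(denom) < 1e-9 * x)
    stop_invalid("degenerate denominator: unisensory biases cancel the conflict")
  structure(list(w_a_emp = (pse_av_conflict - cap_v) / denom, variant = side,
                 inputs_used = list(pse_av = pse_av_conflict, pse_a = pse_a,
                                    pse_v = pse_v, x = x)),
            class = "weight_estimate")
}

#' Per-participant estimates and predictions from a joint fit
#'
#' Convenience extractor: derives the MLE prediction (weights, fused
#' variance, conflict PSEs) and the empirical weight/variance estimates from
#' a fitted 5-condition model.
#'
#' @param fit an `avfuse_fit` over A, V, AV0, AVp, AVm.
#' @param disparity audiovisual disparity magnitude used in the experiment.
#' @return One-row data.frame: `sigma_a`, `sigma_v`, `sigma_av_emp`,
#'   `sigma_av_mle`, `w_a_emp`, `w_a_mle`, PSEs, `lapse`, `eta`, and (for the
#'   free-slope control fit) sided weight estimates.
#' @export
participant_estimates <- function(fit, disparity) {
  s2a <- fit$sigma2[["A"]]; s2v <- fit$sigma2[["V"]]
  pred <- mle_prediction(s2a, s2v, disparity,
                         pse_congruent = fit$alpha[["AV0"]])
  sigma_av_emp <- if (fit$shared_av_slope) fit$sigma[["AV"]] else
    sqrt(mean(fit$sigma2[c("AV0", "AVp", "AVm")]))
  out <- data.frame(
    sigma_a = sqrt(s2a), sigma_v = sqrt(s2v),
    sigma_av_emp = sigma_av_emp,
    sigma_av_mle = sqrt(pred$sigma2_av_mle),
    w_a_emp = empirical_weight_pooled(fit$alpha[["AVp"]], fit$alpha[["AVm"]],
                                      disparity)$w_a_emp,
    w_a_mle = pred$w_a_mle,
    pse_a = fit$alpha[["A"]], pse_v = fit$alpha[["V"]],
    pse_av0 = fit$alpha[["AV0"]], pse_avp = fit$alpha[["AVp"]],
    pse_avm = fit$alpha[["AVm"]],
    pse_avp_mle = pred$pse_avp_mle, pse_avm_mle = pred$pse_avm_mle,
    lapse = fit$lapse, eta = fit$eta, loglik = fit$loglik
  )
  if (!fit$shared_av_slope) {
    out$sigma_av_alvr <- fit$sigma[["AVp"]]
    out$sigma_av_vlar <- fit$sigma[["AVm"]]
    out$sigma_av_congr <- fit$sigma[["AV0"]]
    out$w_a_alvr <- empirical_weight_sided(fit$alpha[["AVp"]],
                                           fit$alpha[["A"]], fit$alpha[["V"]],
                                           disparity, "ALVR")$w_a_emp
    out$w_a_vlar <- empirical_weight_sided(fit$alpha[["AVm"]],
                                           fit$alpha[["A"]], fit$alpha[["V"]],
                                           disparity, "VLAR")$w_a_emp
  }
  out
}
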