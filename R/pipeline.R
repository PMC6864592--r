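# Cohort-level replication pipeline: simulate participants one at a time
# through the three-session protocol (auditory JND measurement, staircase
# matching of visual reliability, confirmation, main experiment), screen
# exclusions, replace excluded participants until the target sample size is
# reached, then run fits, predictions, bootstrap and the group battery.

#' Cohort configuration
#'
#' Defaults reproduce the study's stated world: 36 included participants,
#' 40 trials per (condition, location) cell in the main experiment, 20 in
#' session 1, disparity one auditory JND, JND-scaled probe locations, lapse
#' .02 and overdispersion .10 for the generative observers, eye-tracking
#' trial-exclusion rate 3%.
#'
#' @param n_target included participants (default 36).
#' @param n_per_cell main-experiment trials per cell (default 40).
#' @param n_per_cell_s1 session-1 trials per cell (default 20).
#' @param master_seed integer master seed; the run is fully reproducible
#'   from it.
#' @param policy observer integration policy for the cohort.
#' @param weight_deviation for `policy = "fixed_weight"`: auditory weight is
#'   `0.5 - weight_deviation` (matched reliabilities).
#' @param jnd_a_mean,jnd_a_sdlog lognormal population distribution of the
#'   auditory JND (deg).
#' @param bias_sd SD of the unisensory localization biases (deg).
#' @param lapse,eta generative lapse rate and overdispersion scale.
#' @param blob_to_sigma visual noise per unit blob SD (`sigma_v = c * blob`).
#' @param sim_mode `"cell_beta"` or `"trialwise"` main-experiment generator.
#' @param n_boot parametric-bootstrap replicates for the main-experiment
#'   goodness of fit, CIs and contrasts (study value 5000; scale down for
#'   speed).
#' @param n_boot_s1 bootstrap replicates for the session-1 screening fits.
#' @param trial_exclusion_rate probability a main-experiment trial is
#'   flagged excluded (eye-tracking surrogate).
#' @param include_no_interest also generate the variable-blob-size trials
#'   that are written but never analysed.
#' @param control_fit also run the 5-slope control fit (needed for the
#'   repeated-measures ANOVA and sided weights).
#' @param replacement_budget maximum simulated participants before the run
#'   is declared infeasible (default `3 * n_target`).
#' @param out_dir optional output directory for tidy CSV / JSON artifacts.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_target = 36, n_per_cell = 40, n_per_cell_s1 = 20,
                          master_seed = 1,
                          policy = c("mle", "switching", "fixed_weight"),
                          weight_deviation = 0,
                          jnd_a_mean = 5, jnd_a_sdlog = 0.2, bias_sd = 0.5,
                          lapse = 0.02, eta = 0.1, blob_to_sigma = 0.25,
                          sim_mode = c("cell_beta", "trialwise"),
                          n_boot = 500, n_boot_s1 = 100,
                          trial_exclusion_rate = 0.03,
                          include_no_interest = TRUE, control_fit = TRUE,
                          replacement_budget = NULL, out_dir = NULL) {
  if (n_target < 2) stop_invalid("`n_target` must be >= 2")
  structure(list(
    n_target = n_target, n_per_cell = n_per_cell,
    n_per_cell_s1 = n_per_cell_s1, master_seed = master_seed,
    policy = match.arg(policy), weight_deviation = weight_deviation,
    jnd_a_mean = jnd_a_mean, jnd_a_sdlog = jnd_a_sdlog, bias_sd = bias_sd,
    lapse = lapse, eta = eta, blob_to_sigma = blob_to_sigma,
    sim_mode = match.arg(sim_mode), n_boot = n_boot, n_boot_s1 = n_boot_s1,
    trial_exclusion_rate = trial_exclusion_rate,
    include_no_interest = include_no_interest, control_fit = control_fit,
    replacement_budget = replacement_budget %||% (3 * n_target),
    out_dir = out_dir), class = "cohort_config")
}

# Auditory accuracy at the +-10 deg probes of the first session-1 series.
accuracy_at_10 <- function(counts_a) {
  i_pos <- which(counts_a$x == 10); i_neg <- which(counts_a$x == -10)
  (counts_a$k[i_pos] + (counts_a$n[i_neg] - counts_a$k[i_neg])) /
    (counts_a$n[i_pos] + counts_a$n[i_neg])
}

fit_gof_p <- function(fit, n_boot, seed) {
  if (n_boot <= 0) return(NA_real_)
  boot <- parametric_bootstrap(fit, n_boot = n_boot, seed = seed)
  gof_test(boot)$p_value
}

#' Apply the exclusion screen to a participant record
#'
#' Pre-stage (after session 1): auditory accuracy >= 90% at +-10 deg;
#' predicted fused variance at most two thirds of the smaller unisensory
#' variance (reliability matching succeeded); lapse <= .06 and goodness of
#' fit p >= .05 for both session-1 unisensory fits.  Post-stage (after the
#' main experiment): lapse <= .06 and goodness of fit p >= .05 for the joint
#' fit.  Reason codes are appended, never overwritten.
#'
#' @param record participant record (as built by [simulate_participant()]).
#' @param stage `"pre"` or `"post"`.
#' @return The updated record (`$excluded`, `$reasons`).
#' @export
screen_exclusions <- function(record, stage = c("pre", "post")) {
  stage <- match.arg(stage)
  reasons <- character(0)
  if (stage == "pre") {
    if (record$acc10 < 0.90) reasons <- c(reasons, "auditory_accuracy")
    s2a <- record$fit_a_s1$sigma2[["A"]]
    s2v <- record$fit_v_s1$sigma2[["V"]]
    if (mle_fused_variance(s2a, s2v) > (2 / 3) * min(s2a, s2v))
      reasons <- c(reasons, "variance_matching")
    if (record$fit_a_s1$lapse > 0.06 || record$fit_v_s1$lapse > 0.06)
      reasons <- c(reasons, "lapse")
    gofs <- c(record$gof_p_a_s1, record$gof_p_v_s1)
    if (any(!is.na(gofs) & gofs < 0.05)) reasons <- c(reasons, "gof")
  } else {
    if (record$fit_main$lapse > 0.06) reasons <- c(reasons, "lapse_main")
    if (!is.na(record$gof_p_main) && record$gof_p_main < 0.05)
      reasons <- c(reasons, "gof_main")
  }
  record$reasons <- c(record$reasons, reasons)
  record$excluded <- length(record$reasons) > 0
  record
}

#' Simulate one participant through the full protocol
#'
#' Runs the desk-scale version of the three-session flow: session-1 auditory
#' JND measurement (fixed locations, then individualized refinement), six
#' adaptive staircases pooled into the matched blob size, the visual
#' confirmation series, the pre-stage exclusion screen, then (if not
#' excluded) the main experiment, the joint constrained fit, the parametric
#' bootstrap and the post-stage screen.
#'
#' @param config a [cohort_config()].
#' @param id participant identifier.
#' @param seed participant seed.
#' @return A participant record (list) with trial table, fits, estimates,
#'   bootstrap and exclusion flags.
#' @export
simulate_participant <- function(config, id, seed) {
  set.seed(seed)
  jnd_true <- stats::rlnorm(1, log(config$jnd_a_mean), config$jnd_a_sdlog)
  sigma_a <- jnd_true / sqrt(2)
  bias_a <- stats::rnorm(1, 0, config$bias_sd)
  bias_v <- stats::rnorm(1, 0, config$bias_sd)
  w_a_fixed <- if (config$policy == "fixed_weight")
    0.5 - config$weight_deviation
  make_obs <- function(sigma_v) {
    observer_spec(sigma_a, sigma_v, bias_a, bias_v, config$lapse, config$eta,
                  config$policy, w_a_fixed, seed = seed)
  }
  # visual noise prior to matching: start wide (blob 40 deg track upper end)
  obs0 <- make_obs(sigma_v = config$blob_to_sigma * 10)

  record <- list(id = id, seed = seed, excluded = FALSE,
                 reasons = character(0),
                 true = list(jnd_a = jnd_true, sigma_a = sigma_a,
                             bias_a = bias_a, bias_v = bias_v))

  # --- session 1: auditory series on fixed locations
  fixed_locs <- c(0, -1, 1, -2, 2, -3, 3, -5, 5, -7, 7, -10, 10)
  des_fixed <- structure(list(probe_locations = sort(fixed_locs),
                              disparity = 1, n_per_cell = config$n_per_cell_s1,
                              conditions = "A", jnd_a = NA),
                         class = "experiment_design")
  counts_a1 <- simulate_counts(obs0, des_fixed)[["A"]]
  record$acc10 <- accuracy_at_10(counts_a1)
  fit_a1 <- fit_conditions(list(counts_a1))
  jnd1 <- 1 / fit_a1$beta[["A"]]

  # refinement on individualized locations
  des_a2 <- make_design(jnd1, config$n_per_cell_s1)
  des_a2$conditions <- "A"
  counts_a2 <- simulate_counts(obs0, des_a2)[["A"]]
  fit_a2 <- fit_conditions(list(counts_a2))
  jnd_a <- 1 / fit_a2$beta[["A"]]
  record$fit_a_s1 <- fit_a2
  record$jnd_a <- jnd_a

  # --- staircase matching of the visual blob size
  locs <- c(0.5, 0.85, 1.2) * jnd_a
  u_values <- c(1, 2, 4)
  targets <- vapply(locs, function(L) {
    pa <- list(alpha = 0, beta = fit_a2$beta[["A"]], lapse = fit_a2$lapse)
    psi(L, pa)  # symmetric accuracy target at +-L
  }, numeric(1))
  stairs <- list()
  for (i in seq_along(locs)) {
    for (start in c(2, 40)) {
      st <- staircase_state(start, u = u_values[i],
                            target_fraction = targets[i])
      p_corr <- function(blob) {
        sv <- config$blob_to_sigma * blob
        obs0$lapse + (1 - 2 * obs0$lapse) *
          stats::pnorm(locs[i] / (sv * sqrt(2)))
      }
      stairs[[length(stairs) + 1L]] <- run_staircase(st, p_corr)
    }
  }
  record$blob_sigma <- pool_staircases(stairs)
  sigma_v <- config$blob_to_sigma * record$blob_sigma
  obs <- make_obs(sigma_v)
  record$true$sigma_v <- sigma_v

  # --- visual confirmation series (constant blob size)
  des_v <- make_design(jnd_a, config$n_per_cell_s1)
  des_v$conditions <- "V"
  counts_v <- simulate_counts(obs, des_v)[["V"]]
  fit_v <- fit_conditions(list(counts_v))
  record$fit_v_s1 <- fit_v
  record$gof_p_a_s1 <- fit_gof_p(fit_a2, config$n_boot_s1, seed + 10001L)
  record$gof_p_v_s1 <- fit_gof_p(fit_v, config$n_boot_s1, seed + 20002L)

  record <- screen_exclusions(record, "pre")
  if (record$excluded) return(record)

  # --- main experiment
  design <- make_design(jnd_a, config$n_per_cell)
  record$design <- design
  counts <- simulate_counts(obs, design, mode = config$sim_mode)
  trials <- counts_to_trials(counts, id, session = 2L,
                             disparity = design$disparity,
                             blob_sigma = record$blob_sigma)
  if (config$include_no_interest) {
    trials <- rbind(trials,
                    no_interest_trials(obs, design, id, record$blob_sigma,
                                       config$blob_to_sigma))
  }
  if (config$trial_exclusion_rate > 0) {
    trials$excluded <- as.integer(
      stats::runif(nrow(trials)) < config$trial_exclusion_rate)
  }
  record$trials <- trials
  counts_used <- tally_counts(trials)
  fit_main <- fit_joint(counts_used)
  record$fit_main <- fit_main

  boot <- NULL
  if (config$n_boot > 0) {
    boot <- parametric_bootstrap(fit_main, n_boot = config$n_boot,
                                 seed = seed + 30003L,
                                 disparity = design$disparity)
    record$gof_p_main <- gof_test(boot)$p_value
  } else {
    record$gof_p_main <- NA_real_
  }
  record$boot <- boot
  record <- screen_exclusions(record, "post")
  if (record$excluded) return(record)

  record$estimates <- participant_estimates(fit_main, design$disparity)
  if (config$control_fit) {
    fit_ctrl <- fit_joint(counts_used,
                          constraints = list(shared_av_slope = FALSE))
    record$fit_control <- fit_ctrl
    record$estimates_control <- participant_estimates(fit_ctrl,
                                                      design$disparity)
  }
  record
}

# "Trials of no interest": variable blob size, generated per trial, written
# to the table but never tallied (of_interest = 0).
no_interest_trials <- function(obs, design, id, blob_sigma, blob_to_sigma) {
  xs <- design$probe_locations
  n <- design$n_per_cell
  one_block <- function(condition, reps) {
    x <- rep(xs, each = n * reps)
    blob <- stats::runif(length(x), 0.5 * blob_sigma, 2 * blob_sigma)
    sv <- blob_to_sigma * blob
    p0 <- if (condition == "V") {
      stats::pnorm((x - obs$bias_v) / (sv * sqrt(2)))
    } else { # congruent AV with per-trial visual noise, observer's policy
      w <- observer_weights(obs)
      mu <- w[["w_a"]] * (x - obs$bias_a) + w[["w_v"]] * (x - obs$bias_v)
      se <- sqrt(w[["w_a"]]^2 * obs$sigma_a^2 + w[["w_v"]]^2 * sv^2)
      stats::pnorm(mu / (se * sqrt(2)))
    }
    p <- obs$lapse + (1 - 2 * obs$lapse) * p0
    data.frame(participant_id = id, session = 2L,
               condition = if (condition == "V") "V" else "AV0",
               probe_x_deg = x, disparity_deg = 0, blob_sigma_deg = blob,
               of_interest = 0L,
               response = as.integer(stats::runif(length(x)) < p),
               excluded = 0L)
  }
  rbind(one_block("V", 1L), one_block("AV0", 3L))
}

#' Run the full replication on a synthetic cohort
#'
#' Simulates participants one at a time, screens and replaces exclusions
#' until the target number of included data sets is reached, then runs the
#' group-level battery: one-sided paired tests and Bayes factors for the
#' sensory weights and audiovisual variances, and (when the control fit is
#' enabled) the repeated-measures ANOVA over the per-condition AV noise
#' parameters plus the bias-corrected sided weight tests.
#'
#' @param config a [cohort_config()].
#' @return A list of class `cohort_result` with `tidy` (one row per included
#'   participant), `group` (test reports), `exclusion_log`, `records`
#'   (participant records), `config`.
#' @export
run_replication <- function(config) {
  set.seed(config$master_seed)
  seeds <- sample.int(2^30, config$replacement_budget)
  included <- list()
  exclusion_log <- list()
  attempt <- 0L
  while (length(included) < config$n_target) {
    attempt <- attempt + 1L
    if (attempt > config$replacement_budget)
      stop_invalid("cohort infeasible: replacement budget exhausted (",
                   config$replacement_budget, " attempts)")
    id <- sprintf("sim%03d", attempt)
    rec <- simulate_participant(config, id, seeds[attempt])
    if (rec$excluded) {
      exclusion_log[[length(exclusion_log) + 1L]] <-
        data.frame(id = id, reasons = paste(rec$reasons, collapse = ";"))
    } else {
      included[[length(included) + 1L]] <- rec
    }
  }
  tidy <- do.call(rbind, lapply(included, function(rec) {
    row <- cbind(data.frame(id = rec$id, jnd_a = rec$jnd_a,
                            gof_p = rec$gof_p_main),
                 rec$estimates)
    if (!is.null(rec$estimates_control)) {
      ctrl <- rec$estimates_control[c("sigma_av_alvr", "sigma_av_vlar",
                                      "sigma_av_congr", "w_a_alvr",
                                      "w_a_vlar")]
      row <- cbind(row, ctrl)
    }
    row
  }))
  group <- group_battery(tidy)
  result <- structure(list(tidy = tidy, group = group,
                           exclusion_log = if (length(exclusion_log))
                             do.call(rbind, exclusion_log)
                           else data.frame(id = character(0),
                                           reasons = character(0)),
                           records = included, config = config),
                      class = "cohort_result")
  if (!is.null(config$out_dir)) write_cohort_artifacts(result)
  result
}

group_battery <- function(tidy) {
  if (nrow(tidy) < 3) {
    return(list(note = paste0("group tests need >= 3 included participants; ",
                              "got ", nrow(tidy))))
  }
  out <- list(
    weights = paired_one_sided(tidy$w_a_mle, tidy$w_a_emp, "greater"),
    weights_bf01 = bf01_one_sided(tidy$w_a_mle, tidy$w_a_emp, "greater"),
    variances = paired_one_sided(tidy$sigma_av_emp^2, tidy$sigma_av_mle^2,
                                 "greater"),
    variances_bf01 = bf01_one_sided(tidy$sigma_av_emp^2, tidy$sigma_av_mle^2,
                                    "greater")
  )
  if (!is.null(tidy$sigma_av_alvr)) {
    out$rm_anova <- rm_anova_av_conditions(
      as.matrix(tidy[, c("sigma_av_vlar", "sigma_av_congr", "sigma_av_alvr")]))
    out$weights_alvr <- paired_one_sided(tidy$w_a_mle, tidy$w_a_alvr, "greater")
    out$weights_vlar <- paired_one_sided(tidy$w_a_mle, tidy$w_a_vlar, "greater")
  }
  out
}

write_cohort_artifacts <- function(result) {
  dir.create(result$config$out_dir, recursive = TRUE, showWarnings = FALSE)
  tidy_path <- file.path(result$config$out_dir, "participants.csv")
  data.table::fwrite(result$tidy, tidy_path)
  data.table::fwrite(result$exclusion_log,
                     file.path(result$config$out_dir, "exclusions.csv"))
  grp <- result$group
  report <- list(n = nrow(result$tidy))
  if (!is.null(grp$note)) {
    report$note <- grp$note
  } else {
    report$weights <- grp$weights[c("test_used", "statistic", "df", "p", "dz")]
    report$weights_bf01 <- grp$weights_bf01
    report$variances <- grp$variances[c("test_used", "statistic", "df", "p",
                                        "dz")]
    report$variances_bf01 <- grp$variances_bf01
  }
  if (!is.null(grp$rm_anova)) report$rm_anova <- grp$rm_anova
  jsonlite::write_json(report,
                       file.path(result$config$out_dir, "group_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(result)
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("Synthetic cohort replication:", nrow(x$tidy), "included participants,",
      nrow(x$exclusion_log), "excluded/replaced\n")
  if (!is.null(x$group$note)) {
    cat(" ", x$group$note, "\n")
    return(invisible(x))
  }
  cat("\nSensory weights (alternative: predicted > empirical):\n  ")
  print(x$group$weights)
  cat(sprintf("  BF01 = %.3f\n", x$group$weights_bf01))
  cat("\nAV variances (alternative: empirical > predicted):\n  ")
  print(x$group$variances)
  cat(sprintf("  BF01 = %.3f\n", x$group$variances_bf01))
  invisible(x)
}
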