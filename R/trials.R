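# Trial-table plumbing.  One row per trial:
# participant_id, session, condition (A/V/AV0/AVp/AVm), probe_x_deg,
# disparity_deg (signed; +X for AVp, -X for AVm, 0 otherwise),
# blob_sigma_deg, of_interest (0/1), response (0/1; 1 = "probe right"),
# excluded (0/1, e.g. failed fixation).

TRIAL_COLUMNS <- c("participant_id", "session", "condition", "probe_x_deg",
                   "disparity_deg", "blob_sigma_deg", "of_interest",
                   "response", "excluded")

signed_disparity <- function(condition, disparity) {
  ifelse(condition == "AVp", abs(disparity),
         ifelse(condition == "AVm", -abs(disparity), 0))
}

#' Expand condition counts into a trial table
#'
#' Each (condition, location) cell becomes `n` rows, `k` of them with
#' `response = 1` (deterministic order within the cell).
#'
#' @param counts_list list of [condition_counts()].
#' @param participant_id,session identifiers stored with every row.
#' @param disparity audiovisual disparity magnitude (deg).
#' @param blob_sigma visual blob SD used on these trials (deg).
#' @param of_interest,excluded flags stored with every row.
#' @return A data.frame with the canonical trial-table columns.
#' @export
counts_to_trials <- function(counts_list, participant_id = "sim01",
                             session = 2L, disparity = 0, blob_sigma = NA,
                             of_interest = 1L, excluded = 0L) {
  rows <- lapply(counts_list, function(cc) {
    n_tot <- sum(cc$n)
    data.frame(
      participant_id = participant_id, session = session,
      condition = cc$condition,
      probe_x_deg = rep(cc$x, cc$n),
      disparity_deg = signed_disparity(cc$condition, disparity),
      blob_sigma_deg = blob_sigma,
      of_interest = of_interest,
      response = unlist(lapply(seq_along(cc$x), function(i) {
        rep(c(1L, 0L), c(cc$k[i], cc$n[i] - cc$k[i]))
      })),
      excluded = excluded
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a trial table to CSV
#'
#' @param trials data.frame with the canonical trial columns.
#' @param path output file path.
#' @export
write_trials <- function(trials, path) {
  missing <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing))
    stop_invalid("trial table lacks columns: ", paste(missing, collapse = ", "))
  data.table::fwrite(trials[, TRIAL_COLUMNS, drop = FALSE], path)
  invisible(path)
}

#' Read a trial table from CSV
#'
#' @param path CSV file written by [write_trials()] (or matching its schema).
#' @return A data.frame of trials.
#' @export
read_trials <- function(path) {
  trials <- as.data.frame(data.table::fread(path))
  missing <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing))
    stop_invalid("trial table lacks columns: ", paste(missing, collapse = ", "))
  trials
}

#' Tally a trial table into per-condition counts
#'
#' Drops flagged rows (trials of no interest; eye-tracking exclusions) and
#' groups the remainder by condition and probe location.  Rows with a generic
#' `"AV"` label are assigned to AV0/AVp/AVm by the sign of their disparity.
#'
#' @param trials data.frame with the canonical trial columns.
#' @param of_interest_only drop rows with `of_interest == 0` (default TRUE).
#' @param honour_excluded_flag drop rows with `excluded == 1` (default TRUE).
#' @return Named list of [condition_counts()] (conditions present only).
#' @export
tally_counts <- function(trials, of_interest_only = TRUE,
                         honour_excluded_flag = TRUE) {
  bad <- which(!trials$condition %in% c(AV_CONDITIONS, "AV"))
  if (length(bad))
    stop_invalid("unknown condition label at row ", bad[1], ": '",
                 trials$condition[bad[1]], "'")
  bad <- which(!trials$response %in% c(0, 1))
  if (length(bad))
    stop_invalid("non-binary response at row ", bad[1])
  generic <- trials$condition == "AV"
  if (any(generic)) {
    sgn <- sign(trials$disparity_deg[generic])
    trials$condition[generic] <- c("AVm", "AV0", "AVp")[sgn + 2]
  }
  keep <- rep(TRUE, nrow(trials))
  if (of_interest_only) keep <- keep & trials$of_interest == 1
  if (honour_excluded_flag) keep <- keep & trials$excluded == 0
  trials <- trials[keep, , drop = FALSE]
  out <- lapply(split(trials, factor(trials$condition)), function(df) {
    agg_n <- tapply(df$response, df$probe_x_deg, length)
    agg_k <- tapply(df$response, df$probe_x_deg, sum)
    x <- as.numeric(names(agg_n))
    condition_counts(df$condition[1], x, as.vector(agg_n), as.vector(agg_k))
  })
  present <- intersect(AV_CONDITIONS, names(out))
  out[present]
}
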