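#' Count failed attention checks in harm-task records
#'
#' An attention check presents a dominated option (one option has both more
#' money and fewer shocks); choosing the dominated option counts as a fail.
#'
#' @param harm_records One participant's harm-task choice records including
#'   the attention-check trials.
#' @return Integer count of failed checks.
#' @export
check_attention <- function(harm_records) {
  chk <- harm_records[harm_records$is_attention_check, , drop = FALSE]
  if (nrow(chk) == 0L) stop("no attention-check trials in records")
  harm_dominates <- chk$d_money > 0 & chk$d_shocks < 0
  dominant <- ifelse(harm_dominates, "harmful", "helpful")
  sum(chk$choice != dominant)
}

#' Fraction of missed effort-task trials
#'
#' @param effort_records One participant's effort-task choice records.
#' @return Proportion of trials flagged `missed`.
#' @export
check_missed <- function(effort_records) {
  if (nrow(effort_records) == 0L) stop("no effort-task records")
  mean(effort_records$missed)
}

#' Apply performance-based exclusion rules to a cohort
#'
#' A participant is excluded if they failed one or more of the four harm
#' attention checks, or missed strictly more than 10 percent of the effort
#' trials (so 4/48 is retained, 5/48 excluded).  Exclusion removes the
#' participant from every downstream stage.
#'
#' @param cohort A cohort list as returned by [simulate_cohort()] (needs
#'   `trials` and `traits`; any other elements are filtered in step).
#' @param miss_threshold Missed-fraction cutoff; exclusion when strictly
#'   exceeded (default 0.10).
#' @return List with `cohort` (the input with excluded participants removed
#'   from all tables) and `qc` (data frame: `participant_id`,
#'   `attention_fails`, `missed_fraction`, `excluded`, `reason`).
#' @export
apply_exclusions <- function(cohort, miss_threshold = 0.10) {
  trials <- cohort$trials
  ids <- sort(unique(trials$participant_id))
  qc <- do.call(rbind, lapply(ids, function(id) {
    ht <- trials[trials$participant_id == id & trials$task == "harm", ]
    et <- trials[trials$participant_id == id & trials$task == "effort", ]
    if (nrow(ht) == 0L || nrow(et) == 0L)
      stop(sprintf("participant %s lacks records for one of the tasks", id))
    fails <- check_attention(ht)
    mfrac <- check_missed(et)
    att <- fails >= 1L
    mis <- mfrac > miss_threshold
    data.frame(
      participant_id = id, attention_fails = fails, missed_fraction = mfrac,
      excluded = att || mis,
      reason = if (att && mis) "both" else if (att) "attention_check"
               else if (mis) "missed_trials" else "none",
      stringsAsFactors = FALSE)
  }))
  keep <- qc$participant_id[!qc$excluded]
  filt <- cohort
  for (nm in c("trials", "traits", "ground_truth")) {
    if (!is.null(filt[[nm]]))
      filt[[nm]] <- filt[[nm]][filt[[nm]]$participant_id %in% keep, ,
                               drop = FALSE]
  }
  list(cohort = filt, qc = qc)
}
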