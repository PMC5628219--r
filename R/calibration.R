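#' Calibration policy
#'
#' Rules for the unsupervised calibration phase that every client runs
#' simultaneously before the game: a 9-point procedure, success below a
#' 0.5° accuracy threshold, automatic recalibration on failure, and a
#' three-attempt cutoff after which the failure policy applies.
#'
#' @param n_points Calibration points per attempt.
#' @param threshold_deg Accuracy threshold in degrees; an attempt succeeds
#'   when attained accuracy is `< threshold_deg`.
#' @param max_attempts Maximum attempts before `on_failure` applies (>= 1).
#' @param on_failure What to do after exhausting attempts: exclude the
#'   participant, continue without tracking, or abort the whole session.
#' @return A `calibration_policy` list.
#' @export
calibration_policy <- function(n_points = 9L, threshold_deg = 0.5,
                               max_attempts = 3L,
                               on_failure = c("exclude", "continue_untracked",
                                              "abort_session")) {
  stop_if_not_scalar_number(threshold_deg, "threshold_deg", min = 1e-9)
  stop_if_not_scalar_number(max_attempts, "max_attempts", min = 1)
  structure(list(n_points = as.integer(n_points),
                 threshold_deg = threshold_deg,
                 max_attempts = as.integer(max_attempts),
                 on_failure = match.arg(on_failure)),
            class = "calibration_policy")
}

#' Run the calibration flow for one client
#'
#' Attempts are made sequentially and automatically: an attempt whose
#' attained accuracy is at or above the threshold triggers the next attempt
#' with no external intervention, up to `max_attempts`; on exhaustion the
#' policy's failure action determines the final status.
#'
#' @param policy A [calibration_policy()].
#' @param quality_mean,quality_sd Truncated-normal quality model passed to
#'   [simulate_calibration()].
#' @param seed Integer seed (each attempt derives its own sub-seed).
#' @param participant_id Participant id recorded on the outcome.
#' @return A `calibration_outcome` list: `participant_id`, `attempts`
#'   (data frame with one row per attempt), `final_status`
#'   (`"success"`, `"excluded"` or `"untracked"`), `final_accuracy_deg`,
#'   and `abort` (TRUE when the policy aborts the session).
#' @export
run_calibration <- function(policy, quality_mean = 0.4, quality_sd = 0.15,
                            seed = NULL, participant_id = "p01") {
  stopifnot(inherits(policy, "calibration_policy"))
  attempts <- list()
  success <- FALSE
  for (k in seq_len(policy$max_attempts)) {
    a <- simulate_calibration(quality_mean, quality_sd,
                              threshold_deg = policy$threshold_deg,
                              seed = if (is.null(seed)) NULL else child_seed(seed, k),
                              attempt_index = k, points_shown = policy$n_points)
    attempts[[k]] <- data.frame(attempt_index = a$attempt_index,
                                achieved_accuracy_deg = a$achieved_accuracy_deg,
                                points_shown = a$points_shown,
                                success = a$success)
    if (a$success) { success <- TRUE; break }
  }
  attempts <- do.call(rbind, attempts)
  status <- if (success) "success"
            else switch(policy$on_failure,
                        exclude = "excluded",
                        continue_untracked = "untracked",
                        abort_session = "excluded")
  structure(list(
    participant_id = participant_id,
    attempts = attempts,
    final_status = status,
    final_accuracy_deg = attempts$achieved_accuracy_deg[nrow(attempts)],
    abort = !success && policy$on_failure == "abort_session"
  ), class = "calibration_outcome")
}

#' Decide whether and with whom the session starts
#'
#' The game begins only after every registered client's calibration outcome
#' is resolved. Excluded and aborting outcomes are applied to the pairing:
#' by default an excluded participant's partner is removed with them (a
#' two-player game cannot run one-sided); re-pairing is not attempted.
#'
#' @param outcomes List of `calibration_outcome` objects, one per client.
#' @param pairing List of length-2 character vectors of participant ids.
#' @param remove_partner Remove the partner of an excluded participant
#'   (default TRUE).
#' @return A list: `proceed` (logical), `pairing` (retained pairs),
#'   `active` (tracked participants), `untracked`, `excluded`, `aborted`.
#' @export
calibration_gate <- function(outcomes, pairing, remove_partner = TRUE) {
  status <- vapply(outcomes, function(o) o$final_status, character(1))
  ids <- vapply(outcomes, function(o) o$participant_id, character(1))
  names(status) <- ids
  aborted <- any(vapply(outcomes, function(o) isTRUE(o$abort), logical(1)))
  excluded <- ids[status == "excluded"]
  untracked <- ids[status == "untracked"]
  keep <- if (aborted) list() else Filter(function(p) {
    if (remove_partner) !any(p %in% excluded) else all(!p %in% excluded)
  }, pairing)
  active <- setdiff(unlist(keep), excluded)
  list(proceed = !aborted && length(keep) > 0L,
       pairing = keep, active = active,
       untracked = intersect(untracked, active),
       excluded = excluded, aborted = aborted)
}
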