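#' Session configuration
#'
#' Everything the coordinator needs to run one session: how many clients
#' may arrive, how they are paired, the game structure, screen geometry,
#' calibration policy, which screens are recorded, and an optional
#' gaze-contingent barrier. The session proceeds with however many clients
#' actually arrive by the registration deadline.
#'
#' @param n_participants Maximum number of prepared client slots (>= 2).
#' @param pairing Optional list of length-2 participant-id vectors; by
#'   default arrivals are paired in registration order and pairs stay fixed
#'   across games.
#' @param n_games,n_rounds Games per session and rounds per game.
#' @param screen_w,screen_h Screen resolution in pixels.
#' @param calibration_policy A [calibration_policy()].
#' @param recording_windows Screens during which gaze is recorded (subset
#'   of `c("contribution", "feedback")`).
#' @param barrier Optional [barrier_spec()] applied to the feedback screen.
#' @param game A [game_config()].
#' @param seed Session seed; all randomness derives from it.
#' @param registration_deadline_ms Simulated registration window.
#' @param remove_partner_on_exclusion Remove the partner of a
#'   calibration-excluded participant.
#' @param odd_policy With an odd arrival count, `"drop_last"` (default)
#'   drops the last-registered client with a logged notice; `"abort"`
#'   aborts the session.
#' @return A `session_config` list.
#' @export
session_config <- function(n_participants = 20L, pairing = NULL,
                           n_games = 3L, n_rounds = 10L,
                           screen_w = 1920L, screen_h = 1080L,
                           calibration_policy = gazesync::calibration_policy(),
                           recording_windows = c("contribution", "feedback"),
                           barrier = NULL, game = game_config(n_games = n_games,
                                                             n_rounds = n_rounds),
                           seed = 1L, registration_deadline_ms = 30000L,
                           remove_partner_on_exclusion = TRUE,
                           odd_policy = c("drop_last", "abort")) {
  stop_if_not_scalar_number(n_participants, "n_participants", min = 2)
  structure(list(
    n_participants = as.integer(n_participants), pairing = pairing,
    n_games = as.integer(n_games), n_rounds = as.integer(n_rounds),
    screen_w = as.integer(screen_w), screen_h = as.integer(screen_h),
    calibration_policy = calibration_policy,
    recording_windows = recording_windows, barrier = barrier, game = game,
    seed = as.integer(seed),
    registration_deadline_ms = as.integer(registration_deadline_ms),
    remove_partner_on_exclusion = remove_partner_on_exclusion,
    odd_policy = match.arg(odd_policy)
  ), class = "session_config")
}

#' Gaze-contingent barrier specification
#'
#' @param required_aoi_labels Non-empty set of AOI labels every client must
#'   have fixated.
#' @param min_dwell_ms Minimum cumulative dwell per required AOI (ms);
#'   0 means any fixation counts.
#' @param timeout_ms Optional timeout; `fallback` applies when it elapses
#'   before the requirement is met.
#' @param fallback `"hold"` (default) or `"release"` on timeout.
#' @return A `barrier_spec` list.
#' @export
barrier_spec <- function(required_aoi_labels, min_dwell_ms = 0L,
                         timeout_ms = NULL, fallback = c("hold", "release")) {
  if (length(required_aoi_labels) == 0L)
    stop("barrier needs at least one required AOI label", call. = FALSE)
  stop_if_not_scalar_number(min_dwell_ms, "min_dwell_ms", min = 0)
  structure(list(required_aoi_labels = unique(as.character(required_aoi_labels)),
                 min_dwell_ms = as.integer(min_dwell_ms),
                 timeout_ms = timeout_ms, fallback = match.arg(fallback)),
            class = "barrier_spec")
}

#' Register arriving clients and fix the roster
#'
#' The server accepts whatever clients have sent a `register` message by
#' the deadline (up to `expected_max`), assigns participant ids in arrival
#' order and distributes the session epoch. With a pair-based game an odd
#' arrival count is resolved by the configured policy (drop the
#' last-registered client, or abort).
#'
#' @param expected_max Prepared client slots.
#' @param arrivals List of `register` [wire_message()]s, in arrival order.
#' @param odd_policy `"drop_last"` or `"abort"`.
#' @return A `roster` list: `participants` (data frame of `participant_id`,
#'   `client_name`, `registered_t_ms`), `dropped` (client names), `epoch_ms`.
#' @export
register_clients <- function(expected_max, arrivals,
                             odd_policy = c("drop_last", "abort")) {
  odd_policy <- match.arg(odd_policy)
  for (m in arrivals) {
    if (!inherits(m, "wire_message") || m$msg_type != "register")
      stop("arrivals must be register messages", call. = FALSE)
  }
  n <- length(arrivals)
  if (n < 2L)
    stop("session aborted: need at least 2 registered clients, got ", n,
         call. = FALSE)
  if (n > expected_max) arrivals <- arrivals[seq_len(expected_max)]
  n <- length(arrivals)
  dropped <- character(0)
  if (n %% 2L == 1L) {
    if (odd_policy == "abort")
      stop("session aborted: odd number of arrivals (", n,
           ") in a pair-based game", call. = FALSE)
    dropped <- arrivals[[n]]$sender
    arrivals <- arrivals[-n]
    n <- n - 1L
  }
  participants <- data.frame(
    participant_id = sprintf("p%02d", seq_len(n)),
    client_name = vapply(arrivals, function(m) m$sender, character(1)),
    registered_t_ms = vapply(arrivals, function(m) m$t_ms, integer(1)),
    stringsAsFactors = FALSE
  )
  structure(list(participants = participants, dropped = dropped,
                 epoch_ms = 0L), class = "roster")
}

default_pairing <- function(participant_ids) {
  n <- length(participant_ids)
  lapply(seq_len(n %/% 2L), function(k)
    participant_ids[c(2L * k - 1L, 2L * k)])
}

#' Aggregate contributions and build per-pair feedback
#'
#' The server, not the clients, computes each pair's sum and average, and
#' sends both members a feedback message carrying their own and the
#' other's contribution plus the summary statistics.
#'
#' @param contributions Named integer vector (participant id ->
#'   contribution).
#' @param pairing List of length-2 participant-id vectors.
#' @param cfg A [game_config()].
#' @param t_ms Server time stamped on the feedback messages.
#' @param game,round Indices stamped on the behavior rows.
#' @return A list: `messages` (named list of feedback [wire_message()]s,
#'   one per participant), `behavior` (behavior-log rows), `rejected`
#'   (named character vector of rejection reasons, empty when the round
#'   advanced).
#' @export
aggregate_and_broadcast <- function(contributions, pairing,
                                    cfg = game_config(), t_ms = 0L,
                                    game = 1L, round = 1L) {
  ids <- unlist(pairing)
  rejected <- character(0)
  for (id in ids) {
    v <- contributions[[id]]
    if (is.null(v) || is.na(v))
      rejected[id] <- "missing contribution"
    else if (v != round(v) || v < 0 || v > cfg$endowment)
      rejected[id] <- sprintf("contribution %s out of range [0, %d]",
                              v, cfg$endowment)
  }
  if (length(rejected))
    return(list(messages = list(), behavior = NULL, rejected = rejected))
  msgs <- list()
  beh <- list()
  for (k in seq_along(pairing)) {
    p <- pairing[[k]]
    rec <- play_round(contributions[[p[1]]], contributions[[p[2]]], cfg)
    pair_id <- paste(p, collapse = "-")
    for (side in 1:2) {
      me <- p[side]; other <- p[3 - side]
      own <- contributions[[me]]; oth <- contributions[[other]]
      msgs[[me]] <- wire_message("feedback", "server", t_ms, list(
        own = own, other = oth, sum = rec$sum, average = rec$average,
        game = game, round = round
      ))
      beh[[length(beh) + 1L]] <- data.frame(
        pair_id = pair_id, game = as.integer(game), round = as.integer(round),
        participant_id = me, contribution = as.integer(own),
        sum = rec$sum, average = rec$average,
        payoff = cfg$endowment - own + cfg$mpcr * rec$sum,
        stringsAsFactors = FALSE
      )
    }
  }
  list(messages = msgs, behavior = do.call(rbind, beh),
       rejected = rejected)
}

#' Evaluate a gaze-contingent barrier
#'
#' The barrier releases at the first instant every client has, for every
#' required AOI, accumulated at least `min_dwell_ms` of fixation time (and
#' at least one fixation). Evaluation is on fixation events: the
#' requirement is met at the end of the fixation whose inclusion satisfies
#' it. If a timeout elapses first, the configured fallback applies.
#'
#' @param spec A [barrier_spec()].
#' @param fixation_feeds Named list (one entry per client) of labeled
#'   fixation data frames (`start_ms`, `end_ms`, `duration_ms`,
#'   `aoi_label`).
#' @param known_labels Optional character vector of valid AOI labels; the
#'   spec is validated against it.
#' @return A list: `released`, `t_release` (NA when held), `timed_out`,
#'   `per_client` (completion time per client, NA when never satisfied).
#' @export
gaze_barrier <- function(spec, fixation_feeds, known_labels = NULL) {
  stopifnot(inherits(spec, "barrier_spec"))
  if (!is.null(known_labels) &&
      !all(spec$required_aoi_labels %in% known_labels))
    stop("barrier references unknown AOI labels: ",
         paste(setdiff(spec$required_aoi_labels, known_labels),
               collapse = ", "), call. = FALSE)
  completion <- vapply(fixation_feeds, function(fx) {
    per_aoi <- vapply(spec$required_aoi_labels, function(lab) {
      f <- fx[!is.na(fx$aoi_label) & fx$aoi_label == lab, , drop = FALSE]
      if (nrow(f) == 0L) return(NA_real_)
      f <- f[order(f$end_ms), , drop = FALSE]
      cum <- cumsum(f$duration_ms)
      hit <- which(cum >= spec$min_dwell_ms)
      if (!length(hit)) NA_real_ else as.numeric(f$end_ms[hit[1]])
    }, numeric(1))
    if (anyNA(per_aoi)) NA_real_ else max(per_aoi)
  }, numeric(1))
  satisfied <- !anyNA(completion)
  t_done <- if (satisfied) max(completion) else NA_real_
  timed_out <- !is.null(spec$timeout_ms) &&
    (!satisfied || t_done > spec$timeout_ms)
  released <- if (timed_out) spec$fallback == "release" else satisfied
  t_release <- if (!released) NA_real_
               else if (timed_out) as.numeric(spec$timeout_ms) else t_done
  list(released = released, t_release = t_release, timed_out = timed_out,
       per_client = completion)
}

#' Recording windows from an event log
#'
#' Pairs each `recording_on` event with the next `recording_off` for the
#' same participant.
#'
#' @param events Event-log data frame.
#' @return Data frame of `participant_id`, `on_ms`, `off_ms`.
#' @export
recorded_windows <- function(events) {
  out <- lapply(split(events, events$participant_id), function(df) {
    df <- df[df$kind %in% c("recording_on", "recording_off"), , drop = FALSE]
    df <- df[order(df$t_ms), , drop = FALSE]
    ons <- df$t_ms[df$kind == "recording_on"]
    offs <- df$t_ms[df$kind == "recording_off"]
    n <- min(length(ons), length(offs))
    if (n == 0L) return(NULL)
    data.frame(participant_id = df$participant_id[1],
               on_ms = ons[seq_len(n)], off_ms = offs[seq_len(n)],
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(participant_id = character(0), on_ms = integer(0),
                      off_ms = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Keep only gaze samples that fall inside recording windows
#'
#' Samples arriving while a client's recording is off are not logged; this
#' applies that rule to a sample stream. A sample at `t` is kept when some
#' window of its participant has `on_ms <= t < off_ms`.
#'
#' @param samples Gaze-sample data frame.
#' @param windows Data frame as returned by [recorded_windows()].
#' @return The filtered sample data frame.
#' @export
filter_recorded <- function(samples, windows) {
  if (nrow(samples) == 0L) return(samples)
  keep <- logical(nrow(samples))
  for (k in seq_len(nrow(windows))) {
    keep <- keep | (samples$participant_id == windows$participant_id[k] &
                      samples$t_ms >= windows$on_ms[k] &
                      samples$t_ms < windows$off_ms[k])
  }
  samples[keep, , drop = FALSE]
}
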