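#' Run a complete simulated session
#'
#' Drives the full star-network flow in simulated time: registration with
#' a deadline, simultaneous unsupervised calibration under the session's
#' policy, then `n_games x n_rounds` of the two-player public goods game —
#' contribution screen, server-side aggregation, feedback screen, optional
#' gaze-contingent barrier — with gaze recorded only during the configured
#' screens. Every logical message travels client<->server through the wire
#' codec (gaze samples are batched into one `gaze` message per screen),
#' and the routing log records each hop, so the star topology is checkable
#' after the fact. Deterministic given `seed`.
#'
#' @param config A [session_config()].
#' @param agents List of [agent_spec()]s (the prepared clients; how many
#'   arrive is taken from `length(agents)`).
#' @param seed Session seed (defaults to `config$seed`).
#' @param dir Optional directory; when given, logs are written as
#'   `gaze.csv`, `events.csv`, `behavior.csv`, `truth.csv`, `agents.csv`
#'   and `config.json` under it.
#' @return A `gazesync_session` list: `config`, `roster`, `pairing`,
#'   `agents` (data frame incl. `true_w`), `calibration` (outcomes),
#'   `gaze`, `events`, `behavior`, `truth` (scripted fixations with
#'   intended labels), `clicks`, `routing`, `layouts`, `completed`.
#' @export
generate_session <- function(config, agents, seed = NULL, dir = NULL) {
  stopifnot(inherits(config, "session_config"))
  seed <- seed %||% config$seed
  if (length(agents) < 2L)
    stop("need at least 2 agents", call. = FALSE)

  routing <- new.env(parent = emptyenv())
  routing$log <- list()
  transmit <- function(from, to, msg) {
    if (from != "server" && to != "server")
      stop("star topology violated: ", from, " -> ", to, call. = FALSE)
    m <- decode_message(encode_message(msg))
    routing$log[[length(routing$log) + 1L]] <-
      data.frame(from = from, to = to, msg_type = m$msg_type, t_ms = m$t_ms,
                 stringsAsFactors = FALSE)
    m
  }

  layouts <- list(contribution = build_layout("contribution",
                                              config$screen_w, config$screen_h),
                  feedback = build_layout("feedback",
                                          config$screen_w, config$screen_h))
  tracker <- tracker_config()
  sd_px <- tracker$accuracy_deg * tracker$px_per_deg

  with_seed(seed, {
    ## -- registration ------------------------------------------------------
    arrive_t <- sort(as.integer(runif(length(agents), 0,
                                      min(5000, config$registration_deadline_ms))))
    reg_msgs <- lapply(seq_along(agents), function(k)
      transmit(agents[[k]]$participant_id, "server",
               wire_message("register", agents[[k]]$participant_id,
                            arrive_t[k])))
    roster <- register_clients(config$n_participants, reg_msgs,
                               config$odd_policy)
    ids <- roster$participants$participant_id
    spec_of <- stats::setNames(
      agents[match(roster$participants$client_name,
                   vapply(agents, `[[`, character(1), "participant_id"))], ids)
    for (id in ids)
      transmit("server", id, wire_message("ack", "server",
                                          config$registration_deadline_ms,
                                          list(participant_id = id, epoch_ms = 0)))
    pairing <- config$pairing %||% default_pairing(ids)

    events <- list()
    gaze <- list()
    truth <- list()
    clicks <- list()
    behavior <- list()

    ## -- simultaneous calibration -----------------------------------------
    t_cal <- config$registration_deadline_ms
    attempt_len <- 15000L
    outcomes <- list()
    for (id in ids) {
      transmit("server", id, wire_message("calibrate", "server", t_cal))
      sp <- spec_of[[id]]
      out <- run_calibration(config$calibration_policy,
                             quality_mean = sp$cal_quality_mean,
                             quality_sd = sp$cal_quality_sd,
                             participant_id = id)
      outcomes[[id]] <- out
      for (k in seq_len(nrow(out$attempts)))
        events[[length(events) + 1L]] <- event_record(
          id, t_cal + k * attempt_len, "calibration_result",
          list(attempt = k,
               accuracy_deg = out$attempts$achieved_accuracy_deg[k],
               success = out$attempts$success[k]))
      transmit(id, "server",
               wire_message("calibration_outcome", id,
                            t_cal + nrow(out$attempts) * attempt_len,
                            list(status = out$final_status,
                                 accuracy_deg = out$final_accuracy_deg)))
    }
    t_cal_done <- t_cal + attempt_len *
      max(vapply(outcomes, function(o) nrow(o$attempts), integer(1)))
    gate <- calibration_gate(outcomes, pairing,
                             remove_partner = config$remove_partner_on_exclusion)

    finish <- function(completed) {
      sess <- structure(list(
        config = config, roster = roster, pairing = gate$pairing,
        agents = data.frame(
          participant_id = ids,
          client_name = roster$participants$client_name,
          true_w = vapply(spec_of, `[[`, numeric(1), "true_w"),
          strategy = vapply(spec_of, `[[`, character(1), "strategy"),
          stringsAsFactors = FALSE),
        calibration = outcomes,
        gaze = if (length(gaze)) as.data.frame(data.table::rbindlist(gaze))
               else empty_gaze(),
        events = if (length(events)) as.data.frame(data.table::rbindlist(events))
                 else empty_events(),
        behavior = if (length(behavior))
                     as.data.frame(data.table::rbindlist(behavior))
                   else NULL,
        truth = if (length(truth)) as.data.frame(data.table::rbindlist(truth))
                else NULL,
        clicks = if (length(clicks)) as.data.frame(data.table::rbindlist(clicks))
                 else NULL,
        routing = as.data.frame(data.table::rbindlist(routing$log)),
        layouts = layouts, completed = completed
      ), class = "gazesync_session")
      sess$events <- sess$events[order(sess$events$participant_id,
                                       sess$events$t_ms), , drop = FALSE]
      rownames(sess$events) <- NULL
      if (!is.null(dir)) write_session(sess, dir)
      sess
    }

    if (!gate$proceed) return(finish(FALSE))
    active <- gate$active
    tracked <- setdiff(active, gate$untracked)

    ## -- games -------------------------------------------------------------
    t <- t_cal_done + 1000L
    fb_labels <- layouts$feedback$aois$label
    for (game in seq_len(config$n_games)) {
      prev <- list()  # per participant: previous round's own contribution
      for (round in seq_len(config$n_rounds)) {
        ## contribution screen
        t0 <- t
        contribs <- list()
        click_ts <- integer(0)
        for (id in active) {
          sp <- spec_of[[id]]
          partner <- setdiff(unlist(Filter(function(p) id %in% p,
                                           gate$pairing)), id)
          c_id <- next_contribution(sp, prev[[id]] %||% NA,
                                    prev[[partner]] %||% NA, round)
          contribs[[id]] <- c_id
          transmit("server", id,
                   wire_message("show_screen", "server", t0,
                                list(screen = "contribution",
                                     game = game, round = round)))
          events[[length(events) + 1L]] <- event_record(
            id, t0, "screen_shown",
            list(screen = "contribution", game = game, round = round))
          rec_on <- "contribution" %in% config$recording_windows
          if (rec_on)
            events[[length(events) + 1L]] <- event_record(
              id, t0, "recording_on", list(screen = "contribution"))
          sg <- script_gaze_for_round(sp, layouts$contribution, "contribution",
                                      t0_ms = t0 + 200L,
                                      clicked_label = as.character(c_id))
          truth[[length(truth) + 1L]] <- data.frame(
            participant_id = id, game = game, round = round,
            screen = "contribution",
            onset_ms = sg$script$onset_ms, offset_ms = sg$script$offset_ms,
            label = sg$script$label, stringsAsFactors = FALSE)
          if (rec_on && id %in% tracked) {
            smp <- stream_gaze(sg$script, tracker, participant_id = id)
            gaze[[length(gaze) + 1L]] <- smp
            transmit(id, "server",
                     wire_message("gaze", id, sg$click_t_ms,
                                  list(n_samples = nrow(smp),
                                       screen = "contribution")))
          }
          events[[length(events) + 1L]] <- event_record(
            id, sg$click_t_ms, "click",
            list(label = as.character(c_id), game = game, round = round))
          clicks[[length(clicks) + 1L]] <- data.frame(
            participant_id = id, t_ms = sg$click_t_ms,
            clicked_label = as.character(c_id), game = game, round = round,
            stringsAsFactors = FALSE)
          transmit(id, "server",
                   wire_message("submit_contribution", id, sg$click_t_ms,
                                list(contribution = c_id,
                                     game = game, round = round)))
          click_ts <- c(click_ts, sg$click_t_ms)
        }
        t1 <- max(click_ts) + 200L
        if ("contribution" %in% config$recording_windows)
          for (id in active)
            events[[length(events) + 1L]] <- event_record(
              id, t1, "recording_off", list(screen = "contribution"))

        ## aggregation + feedback
        agg <- aggregate_and_broadcast(contribs, gate$pairing, config$game,
                                       t_ms = t1, game = game, round = round)
        if (length(agg$rejected))
          stop("internal: simulated client submitted an invalid contribution")
        behavior[[length(behavior) + 1L]] <- agg$behavior
        for (id in names(agg$messages)) transmit("server", id, agg$messages[[id]])

        fb_end <- integer(0)
        fb_truth_idx <- integer(0)
        for (id in active) {
          sp <- spec_of[[id]]
          events[[length(events) + 1L]] <- event_record(
            id, t1, "screen_shown",
            list(screen = "feedback", game = game, round = round))
          rec_on <- "feedback" %in% config$recording_windows
          if (rec_on)
            events[[length(events) + 1L]] <- event_record(
              id, t1, "recording_on", list(screen = "feedback"))
          sg <- script_gaze_for_round(sp, layouts$feedback, "feedback",
                                      t0_ms = t1 + 200L)
          truth[[length(truth) + 1L]] <- data.frame(
            participant_id = id, game = game, round = round,
            screen = "feedback",
            onset_ms = sg$script$onset_ms, offset_ms = sg$script$offset_ms,
            label = sg$script$label, stringsAsFactors = FALSE)
          fb_truth_idx <- c(fb_truth_idx, length(truth))
          if (rec_on && id %in% tracked) {
            smp <- stream_gaze(sg$script, tracker, participant_id = id)
            gaze[[length(gaze) + 1L]] <- smp
            transmit(id, "server",
                     wire_message("gaze", id,
                                  sg$script$offset_ms[nrow(sg$script)],
                                  list(n_samples = nrow(smp),
                                       screen = "feedback")))
          }
          fb_end <- c(fb_end, sg$script$offset_ms[nrow(sg$script)])
        }
        t2 <- max(fb_end) + 500L

        ## optional gaze-contingent barrier on the feedback screen
        if (!is.null(config$barrier)) {
          feeds <- lapply(fb_truth_idx, function(k) {
            tr <- truth[[k]]
            data.frame(start_ms = tr$onset_ms, end_ms = tr$offset_ms,
                       duration_ms = tr$offset_ms - tr$onset_ms,
                       aoi_label = tr$label, stringsAsFactors = FALSE)
          })
          names(feeds) <- vapply(fb_truth_idx, function(k)
            truth[[k]]$participant_id[1], character(1))
          res <- gaze_barrier(config$barrier, feeds, known_labels = fb_labels)
          if (res$released) {
            for (id in active) {
              transmit("server", id,
                       wire_message("barrier_release", "server",
                                    as.integer(res$t_release),
                                    list(game = game, round = round)))
              events[[length(events) + 1L]] <- event_record(
                id, as.integer(res$t_release), "barrier_release",
                list(game = game, round = round))
            }
            t2 <- max(t2, as.integer(res$t_release) + 200L)
          }
        }

        if ("feedback" %in% config$recording_windows)
          for (id in active)
            events[[length(events) + 1L]] <- event_record(
              id, t2, "recording_off", list(screen = "feedback"))
        for (id in active) prev[[id]] <- contribs[[id]]
        t <- t2 + 200L
      }
    }
    for (id in active)
      transmit("server", id, wire_message("session_end", "server", t))
    finish(TRUE)
  })
}

#' @export
print.gazesync_session <- function(x, ...) {
  cat(sprintf("gazesync session: %d registered, %d pairs, %s\n",
              nrow(x$roster$participants), length(x$pairing),
              if (x$completed) "completed" else "not started"))
  cat(sprintf("  %d gaze samples, %d events, %d behavior rows\n",
              nrow(x$gaze), nrow(x$events),
              if (is.null(x$behavior)) 0L else nrow(x$behavior)))
  invisible(x)
}

#' Write / read a session directory
#'
#' The on-disk layout is `dir/{gaze.csv, events.csv, behavior.csv,
#' truth.csv, agents.csv, config.json}` — flat CSV logs plus a JSON echo
#' of the configuration.
#'
#' @param session A `gazesync_session`.
#' @param dir Directory (created if missing).
#' @return `write_session` returns `dir` invisibly; `read_session` returns
#'   a list with `gaze`, `events`, `behavior`, `truth`, `agents`.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- session$gaze[order(session$gaze$participant_id, session$gaze$t_ms), ,
                    drop = FALSE]
  write_gaze_log(g, file.path(dir, "gaze.csv"))
  write_event_log(session$events, file.path(dir, "events.csv"))
  beh <- session$behavior
  if (is.null(beh))
    beh <- data.frame(pair_id = character(0), game = integer(0),
                      round = integer(0), participant_id = character(0),
                      contribution = integer(0), sum = integer(0),
                      average = numeric(0), payoff = numeric(0))
  write_behavior_log(beh, file.path(dir, "behavior.csv"))
  if (!is.null(session$truth))
    data.table::fwrite(session$truth, file.path(dir, "truth.csv"))
  data.table::fwrite(session$agents, file.path(dir, "agents.csv"))
  cfg <- session$config
  cfg$calibration_policy <- unclass(cfg$calibration_policy)
  cfg$game <- unclass(cfg$game)
  if (!is.null(cfg$barrier)) cfg$barrier <- unclass(cfg$barrier)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  list(gaze = read_gaze_log(file.path(dir, "gaze.csv")),
       events = read_event_log(file.path(dir, "events.csv")),
       behavior = read_behavior_log(file.path(dir, "behavior.csv")),
       truth = if (file.exists(file.path(dir, "truth.csv")))
         data.table::fread(file.path(dir, "truth.csv"), data.table = FALSE)
       else NULL,
       agents = if (file.exists(file.path(dir, "agents.csv")))
         data.table::fread(file.path(dir, "agents.csv"), data.table = FALSE)
       else NULL)
}
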