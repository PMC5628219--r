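reg <- function(ids) lapply(seq_along(ids), function(k)
  wire_message("register", ids[k], k * 10))

test_that("registration adapts to however many clients arrive", {
  r18 <- register_clients(20, reg(sprintf("c%02d", 1:18)))
  expect_equal(nrow(r18$participants), 18)
  expect_equal(r18$participants$participant_id, sprintf("p%02d", 1:18))

  r2 <- register_clients(20, reg(c("a", "b")))
  expect_equal(nrow(r2$participants), 2)

  expect_error(register_clients(20, reg("only")), "at least 2")
  expect_error(register_clients(20, list()), "at least 2")

  r_odd <- register_clients(20, reg(c("a", "b", "c")))
  expect_equal(nrow(r_odd$participants), 2)
  expect_equal(r_odd$dropped, "c")
  expect_error(register_clients(20, reg(c("a", "b", "c")),
                                odd_policy = "abort"), "odd")
})

test_that("the server aggregates pair contributions and rejects bad input", {
  pairing <- list(c("p01", "p02"))
  out <- aggregate_and_broadcast(list(p01 = 12, p02 = 20), pairing)
  expect_equal(out$messages$p01$body$sum, 32)
  expect_equal(out$messages$p01$body$average, 16)
  expect_equal(out$messages$p01$body$own, 12)
  expect_equal(out$messages$p01$body$other, 20)
  expect_equal(out$messages$p02$body$own, 20)
  expect_equal(nrow(out$behavior), 2)

  zero <- aggregate_and_broadcast(list(p01 = 0, p02 = 0), pairing)
  expect_equal(zero$messages$p01$body$sum, 0)
  expect_equal(zero$messages$p01$body$average, 0)

  bad <- aggregate_and_broadcast(list(p01 = 25, p02 = 3), pairing)
  expect_equal(names(bad$rejected), "p01")
  expect_null(bad$behavior)
  missing <- aggregate_and_broadcast(list(p02 = 3), pairing)
  expect_match(missing$rejected[["p01"]], "missing")
})

test_that("broadcast sums equal an independent replay over many seeded pairs", {
  set.seed(61)
  pairing <- lapply(1:9, function(k) sprintf("p%02d", c(2 * k - 1, 2 * k)))
  contribs <- as.list(sample(0:20, 18, replace = TRUE))
  names(contribs) <- unlist(pairing)
  out <- aggregate_and_broadcast(contribs, pairing)
  beh <- out$behavior
  # replay: recompute each pair's sum from the logged contributions alone
  for (pid in unique(beh$pair_id)) {
    rows <- beh[beh$pair_id == pid, ]
    expect_equal(unique(rows$sum), sum(rows$contribution))
    expect_equal(unique(rows$average), sum(rows$contribution) / 2)
  }
  for (id in names(contribs))
    expect_equal(out$messages[[id]]$body$own, contribs[[id]])
})

test_that("the gaze barrier releases exactly when every client satisfies the dwell rule", {
  feed <- function(labs, starts, durs)
    data.frame(start_ms = starts, end_ms = starts + durs, duration_ms = durs,
               aoi_label = labs, stringsAsFactors = FALSE)
  spec <- barrier_spec(c("A", "B"), min_dwell_ms = 300)

  f1 <- feed(c("A", "B", "A"), c(0, 400, 800), c(200, 350, 150))
  f2 <- feed(c("B", "A", "A"), c(100, 500, 900), c(400, 250, 100))
  # client 1: B done at 750 (350ms >= 300); A needs 200+150 -> done at 950
  # client 2: B done at 500; A needs 250+100 -> done at 1000
  res <- gaze_barrier(spec, list(c1 = f1, c2 = f2))
  expect_true(res$released)
  expect_equal(unname(res$per_client), c(950, 1000))
  expect_equal(res$t_release, 1000)

  # one client never fixates a required AOI: no release, timeout honored
  f3 <- feed("A", 0, 500)
  held <- gaze_barrier(spec, list(c1 = f1, c2 = f3))
  expect_false(held$released)
  to <- gaze_barrier(barrier_spec(c("A", "B"), 300, timeout_ms = 2000,
                                  fallback = "release"),
                     list(c1 = f1, c2 = f3))
  expect_true(to$released)
  expect_true(to$timed_out)
  expect_equal(to$t_release, 2000)

  # min_dwell 0: a single glance at each AOI suffices; both clients have
  # seen A and B by the end of c1's/c2's first A+B visits (both at 750)
  glance <- gaze_barrier(barrier_spec(c("A", "B")), list(c1 = f1, c2 = f2))
  expect_true(glance$released)
  expect_equal(glance$t_release, 750)

  expect_error(gaze_barrier(barrier_spec("Z"), list(c1 = f1),
                            known_labels = c("A", "B")), "unknown AOI")
})

test_that("in-session barrier releases match script-derived completion times", {
  b <- barrier_spec(c("you_round", "you_total", "personb_round",
                      "personb_total"), min_dwell_ms = 0)
  s <- small_session(n = 2, n_games = 1, n_rounds = 4, seed = 77, barrier = b)
  rel <- s$events[s$events$kind == "barrier_release", ]
  tr <- s$truth[s$truth$screen == "feedback", ]
  for (k in seq_len(nrow(rel))) {
    pl <- jsonlite::fromJSON(rel$payload_json[k])
    # independent completion time: per client, the latest first-visit
    # offset over the required AOIs, then the max over clients
    round_tr <- tr[tr$game == pl$game & tr$round == pl$round, ]
    comp <- vapply(split(round_tr, round_tr$participant_id), function(df) {
      firsts <- vapply(b$required_aoi_labels, function(lab) {
        hits <- df$offset_ms[df$label == lab]
        if (length(hits)) min(hits) else NA_real_
      }, numeric(1))
      max(firsts)
    }, numeric(1))
    expect_equal(rel$t_ms[k], max(comp))
  }
})

test_that("recording windows gate what reaches the gaze log", {
  # op-level: a 5 s on-window over a continuous 10 s stream keeps 300 +- 1
  script <- gaze_script(500, 500, 0, 10000)
  s <- stream_gaze(script, tracker_config(), seed = 5)
  win <- data.frame(participant_id = "p01", on_ms = 2000L, off_ms = 7000L)
  kept <- filter_recorded(s, win)
  expect_lte(abs(nrow(kept) - 300), 1)
  expect_true(all(kept$t_ms >= 2000 & kept$t_ms < 7000))
  # two disjoint windows: nothing from the gap
  win2 <- data.frame(participant_id = "p01", on_ms = c(0L, 6000L),
                     off_ms = c(2000L, 8000L))
  kept2 <- filter_recorded(s, win2)
  expect_equal(nrow(kept2[kept2$t_ms >= 2000 & kept2$t_ms < 6000, ]), 0)

  # session-level: recording off for the whole session -> empty gaze log
  s_off <- small_session(n = 2, n_games = 1, n_rounds = 2, seed = 9,
                         recording_windows = character(0))
  expect_equal(nrow(s_off$gaze), 0)
  expect_true(s_off$completed)

  # feedback-only recording: every sample falls inside a logged window
  s_fb <- small_session(n = 2, n_games = 1, n_rounds = 3, seed = 10,
                        recording_windows = "feedback")
  win_fb <- recorded_windows(s_fb$events)
  expect_equal(nrow(filter_recorded(s_fb$gaze, win_fb)), nrow(s_fb$gaze))
})

test_that("clients exchange data only with the server", {
  s <- small_session(n = 4, n_games = 1, n_rounds = 2, seed = 13)
  r <- s$routing
  expect_true(all(r$from == "server" | r$to == "server"))
  expect_false(any(r$from == r$to))
  # every message that crossed the wire survived an encode/decode cycle;
  # the codec would have errored otherwise, so the log is complete
  expect_true(all(r$msg_type %in% gazesync:::MSG_TYPES))
})

test_that("feedback never precedes both pair members' submissions", {
  s <- small_session(n = 4, n_games = 2, n_rounds = 3, seed = 17)
  r <- s$routing
  subs <- r[r$msg_type == "submit_contribution", ]
  fb <- r[r$msg_type == "feedback", ]
  # all submissions of a round precede all feedback of that round: compare
  # by time since rounds are strictly ordered
  expect_true(min(fb$t_ms) >= max(subs$t_ms[subs$t_ms <= min(fb$t_ms)]))
  for (t_fb in unique(fb$t_ms)) {
    n_sub_before <- sum(subs$t_ms <= t_fb)
    expect_equal(n_sub_before %% 4, 0)  # whole rounds only (4 clients)
  }
})

test_that("sessions complete across the supported client counts", {
  for (n in c(2, 18, 20)) {
    s <- generate_session(
      session_config(n_participants = 20, n_games = 1, n_rounds = 2,
                     seed = 100 + n),
      make_agents(n, seed = n))
    expect_true(s$completed)
    expect_equal(length(s$pairing), n %/% 2)
    expect_equal(nrow(s$behavior), n * 2)  # n participants x 2 rounds
  }
})
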