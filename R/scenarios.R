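#' Synthetic agent specification
#'
#' Ground-truth description of one simulated participant: how they
#' contribute (a matching agent with known weight `true_w`, or an erratic
#' probe that contributes uniformly at random — useful for
#' parameter-recovery experiments, where the partner must supply input
#' variation) and how their gaze couples to `true_w` (the share of
#' feedback-screen fixations on their own payoff AOIs is
#' `true_w` plus noise).
#'
#' Round-1 contributions are drawn from a discretized normal with median
#' 12 — typical first-round behavior in a 0–20 public goods game, where
#' contributions start well above half the endowment.
#'
#' @param participant_id Client name used at registration.
#' @param true_w Matching weight in `[0, 1]`.
#' @param behavior_noise_sd Contribution noise sd in points (>= 0).
#' @param round1_mean,round1_sd Round-1 distribution (discretized normal,
#'   clipped to `[0, 20]`).
#' @param gaze_coupling_noise_sd Sd of the noise on the own-AOI fixation
#'   share.
#' @param strategy `"matching"` or `"erratic"` (i.i.d. uniform
#'   contributions).
#' @param cal_quality_mean,cal_quality_sd Calibration quality model for
#'   this participant (degrees; sd 0 forces the outcome).
#' @return An `agent_spec` list.
#' @export
agent_spec <- function(participant_id, true_w = 0.5, behavior_noise_sd = 2,
                       round1_mean = 12, round1_sd = 3,
                       gaze_coupling_noise_sd = 0.05,
                       strategy = c("matching", "erratic"),
                       cal_quality_mean = 0.4, cal_quality_sd = 0.15) {
  stop_if_not_scalar_number(true_w, "true_w", min = 0, max = 1)
  stop_if_not_scalar_number(behavior_noise_sd, "behavior_noise_sd", min = 0)
  stop_if_not_scalar_number(gaze_coupling_noise_sd, "gaze_coupling_noise_sd",
                            min = 0)
  structure(list(participant_id = participant_id, true_w = true_w,
                 behavior_noise_sd = behavior_noise_sd,
                 round1_mean = round1_mean, round1_sd = round1_sd,
                 gaze_coupling_noise_sd = gaze_coupling_noise_sd,
                 strategy = match.arg(strategy),
                 cal_quality_mean = cal_quality_mean,
                 cal_quality_sd = cal_quality_sd),
            class = "agent_spec")
}

# one contribution draw for an agent given the pair's previous round
next_contribution <- function(spec, own_prev, other_prev, round) {
  if (spec$strategy == "erratic") return(sample(0:20, 1L))
  if (round == 1L)
    return(as.integer(clip(round(rnorm(1, spec$round1_mean, spec$round1_sd)),
                           0, 20)))
  as.integer(clip(round(spec$true_w * own_prev +
                          (1 - spec$true_w) * other_prev +
                          rnorm(1, 0, spec$behavior_noise_sd)), 0, 20))
}

#' Simulate a pair's contribution history
#'
#' Round 1 of each game is drawn from each agent's round-1 distribution;
#' from round 2 on, a matching agent plays
#' `clip(round(w * own[t-1] + (1-w) * other[t-1] + noise), 0, 20)` and an
#' erratic agent draws uniformly. History resets at each game boundary.
#' Deterministic given `seed`.
#'
#' @param spec_i,spec_j [agent_spec()]s for the two players.
#' @param n_games,n_rounds Games and rounds per game.
#' @param seed Integer seed.
#' @return A data frame `game`, `round`, `c_i`, `c_j` with the two agents'
#'   ids as attributes `id_i`, `id_j`.
#' @export
simulate_contributions <- function(spec_i, spec_j, n_games = 3L,
                                   n_rounds = 10L, seed = NULL) {
  with_seed(seed, {
    out <- lapply(seq_len(n_games), function(g) {
      ci <- cj <- integer(n_rounds)
      for (t in seq_len(n_rounds)) {
        ci[t] <- next_contribution(spec_i, if (t > 1) ci[t - 1] else NA,
                                   if (t > 1) cj[t - 1] else NA, t)
        cj[t] <- next_contribution(spec_j, if (t > 1) cj[t - 1] else NA,
                                   if (t > 1) ci[t - 1] else NA, t)
      }
      data.frame(game = g, round = seq_len(n_rounds), c_i = ci, c_j = cj)
    })
    res <- do.call(rbind, out)
    attr(res, "id_i") <- spec_i$participant_id
    attr(res, "id_j") <- spec_j$participant_id
    res
  })
}

#' History of one pair member from a pair simulation
#' @param pair_history Result of [simulate_contributions()].
#' @param side `"i"` or `"j"`.
#' @return A history data frame (`game`, `round`, `own`, `other`) usable by
#'   the contribution models.
#' @export
pair_member_history <- function(pair_history, side = c("i", "j")) {
  side <- match.arg(side)
  if (side == "i")
    data.frame(game = pair_history$game, round = pair_history$round,
               own = pair_history$c_i, other = pair_history$c_j)
  else
    data.frame(game = pair_history$game, round = pair_history$round,
               own = pair_history$c_j, other = pair_history$c_i)
}

# scripted fixation durations: plausible decision-task fixations
draw_fix_durations <- function(n) pmax(180, round(rtnorm0(n, 250, 70)))

FEEDBACK_OWN_LABELS <- c("you_round", "you_total")
FEEDBACK_OTHER_LABELS <- c("personb_round", "personb_total")

#' Script one participant's gaze for one screen of one round
#'
#' On the feedback screen the number of fixations is drawn from a normal
#' with mean 17 and sd 9, truncated at 1, and the share directed at the
#' participant's own payoff AOIs is `clip(true_w + noise, 0, 1)`; the rest
#' go to the other player's AOIs. On the contribution screen a handful of
#' option AOIs are inspected and the script's final fixation lands on the
#' AOI the participant clicks.
#'
#' @param spec An [agent_spec()].
#' @param layout The screen's [build_layout()] result.
#' @param screen `"feedback"` or `"contribution"`.
#' @param t0_ms Script start time (ms).
#' @param clicked_label For the contribution screen, the option to end on.
#' @param n_fixations Override the fixation count draw.
#' @return A list: `script` (a [gaze_script()] with intended labels),
#'   `click_t_ms` (contribution screens only, else `NA`).
#' @export
script_gaze_for_round <- function(spec, layout, screen = c("feedback",
                                                           "contribution"),
                                  t0_ms = 0L, clicked_label = NULL,
                                  n_fixations = NULL) {
  screen <- match.arg(screen)
  centers <- aoi_centers(layout)
  if (screen == "feedback") {
    n <- n_fixations %||% max(1L, as.integer(round(rnorm(1, 17, 9))))
    share <- clip(spec$true_w + rnorm(1, 0, spec$gaze_coupling_noise_sd), 0, 1)
    n_own <- as.integer(round(n * share))
    labs <- sample(c(sample(FEEDBACK_OWN_LABELS, n_own, replace = TRUE),
                     sample(FEEDBACK_OTHER_LABELS, n - n_own, replace = TRUE)))
    click_t <- NA_integer_
  } else {
    if (is.null(clicked_label))
      stop("contribution screens need `clicked_label`", call. = FALSE)
    n <- n_fixations %||% sample(3:6, 1L)
    labs <- c(sample(centers$label, n - 1L, replace = TRUE), clicked_label)
  }
  dur <- draw_fix_durations(length(labs))
  onset <- t0_ms + cumsum(c(0L, head(dur, -1L) + 40L))
  idx <- match(labs, centers$label)
  script <- gaze_script(centers$cx[idx], centers$cy[idx],
                        onset, onset + dur, labs)
  if (screen == "contribution") click_t <- script$offset_ms[nrow(script)] + 150L
  list(script = script, click_t_ms = as.integer(click_t))
}
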