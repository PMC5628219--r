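#' Turn a participant-level behavior log into model-ready histories
#'
#' @param behavior Behavior-log data frame
#'   (`pair_id,game,round,participant_id,contribution,sum,average,payoff`).
#' @return Named list (by participant id) of history data frames with
#'   columns `game`, `round`, `own`, `other` (the partner's contribution is
#'   recovered as `sum - contribution`).
#' @export
histories_from_behavior <- function(behavior) {
  out <- lapply(split(behavior, behavior$participant_id), function(df) {
    df <- df[order(df$game, df$round), , drop = FALSE]
    data.frame(game = df$game, round = df$round,
               own = df$contribution, other = df$sum - df$contribution)
  })
  out
}

# dispersion threshold suited to i.i.d. per-sample noise of sd `sd_px`:
# the expected x+y range of ~15 noise samples is about 6.6 sd, so 8 sd
# leaves margin without bridging distinct AOIs (which are separated by
# saccade gaps anyway).
idt_dispersion_for <- function(sd_px) ceiling(8 * sd_px)

#' Analyze a session's logs end to end
#'
#' Runs the offline pipeline on a generated (or read-back) session:
#' detects fixations with I-DT, attributes each fixation to the screen on
#' display when it started (from the `screen_shown` events) and to that
#' screen's AOI, computes dwells, the last-fixation-versus-click
#' correspondence, AOI-role fixation shares on the feedback screen,
#' per-participant and per-round relative attention, fits the matching
#' weight per participant from the behavior log, compares the contribution
#' models, and correlates fitted weights with relative attention.
#'
#' @param session A `gazesync_session`, or the list returned by
#'   [read_session()].
#' @param dispersion_px I-DT dispersion threshold; defaults to 8x the
#'   simulated per-sample noise sd (152 px at 0.5° accuracy and
#'   38 px/°).
#' @param min_duration_ms I-DT minimum duration.
#' @return A `session_analysis` list: `fixations` (labeled, with `screen`,
#'   `game`, `round`), `dwells`, `shares`, `correspondence`, `attention`
#'   (per participant: counts, `ra`), `per_round_ra` (with contribution
#'   difference), `fits` (per participant `w`), `comparison`
#'   ([compare_models()] result), `w_ra` ([correlate_w_ra()] result),
#'   `ra_diff` ([ra_vs_contribution_diff()] result).
#' @export
analyze_session <- function(session, dispersion_px = NULL,
                            min_duration_ms = 100) {
  dispersion_px <- dispersion_px %||%
    idt_dispersion_for(tracker_config()$accuracy_deg *
                         tracker_config()$px_per_deg)
  layouts <- session$layouts %||%
    list(contribution = build_layout("contribution"),
         feedback = build_layout("feedback"))
  gaze <- session$gaze[order(session$gaze$participant_id,
                             session$gaze$t_ms), , drop = FALSE]
  fix <- detect_fixations_idt(gaze, dispersion_px, min_duration_ms)

  ## attribute fixations to screens via screen_shown events
  ev <- session$events
  shows <- ev[ev$kind == "screen_shown", , drop = FALSE]
  if (nrow(shows)) {
    pl <- lapply(shows$payload_json, jsonlite::fromJSON)
    shows$screen <- vapply(pl, `[[`, character(1), "screen")
    shows$game <- vapply(pl, function(p) as.integer(p$game), integer(1))
    shows$round <- vapply(pl, function(p) as.integer(p$round), integer(1))
  }
  fix$screen <- NA_character_
  fix$game <- NA_integer_
  fix$round <- NA_integer_
  for (id in unique(fix$participant_id)) {
    sh <- shows[shows$participant_id == id, , drop = FALSE]
    if (!nrow(sh)) next
    sh <- sh[order(sh$t_ms), , drop = FALSE]
    sel <- fix$participant_id == id
    k <- findInterval(fix$start_ms[sel], sh$t_ms)
    k[k == 0L] <- NA_integer_
    fix$screen[sel] <- sh$screen[k]
    fix$game[sel] <- sh$game[k]
    fix$round[sel] <- sh$round[k]
  }

  labeled <- lapply(c("contribution", "feedback"), function(s) {
    f <- fix[!is.na(fix$screen) & fix$screen == s, , drop = FALSE]
    if (nrow(f) == 0L) return(NULL)
    assign_aois(f, layouts[[s]])
  })
  labeled <- labeled[!vapply(labeled, is.null, logical(1))]
  fix <- if (length(labeled)) do.call(rbind, labeled) else {
    fix$aoi_label <- character(0); fix$aoi_role <- character(0); fix
  }
  fix <- fix[order(fix$participant_id, fix$start_ms), , drop = FALSE]
  rownames(fix) <- NULL

  dwells <- compute_dwells(fix)
  fb <- fix[!is.na(fix$screen) & fix$screen == "feedback", , drop = FALSE]
  shares <- aoi_share_report(fb)

  clicks <- session$clicks
  if (is.null(clicks)) {
    cl <- ev[ev$kind == "click", , drop = FALSE]
    if (nrow(cl)) {
      pl <- lapply(cl$payload_json, jsonlite::fromJSON)
      clicks <- data.frame(participant_id = cl$participant_id, t_ms = cl$t_ms,
                           clicked_label = vapply(pl, `[[`, character(1),
                                                  "label"),
                           stringsAsFactors = FALSE)
    }
  }
  corr <- if (!is.null(clicks) && nrow(clicks))
    last_fixation_correspondence(fix, clicks) else NULL

  ## relative attention, per participant and per round
  ids <- sort(unique(c(fb$participant_id,
                       if (!is.null(session$behavior))
                         session$behavior$participant_id)))
  attention <- do.call(rbind, lapply(ids, function(id) {
    ra <- relative_attention(fb[fb$participant_id == id, , drop = FALSE],
                             FEEDBACK_OWN_LABELS, FEEDBACK_OTHER_LABELS)
    data.frame(participant_id = id, n_fix_own = ra$n_fix_own,
               n_fix_other = ra$n_fix_other, ra = ra$ra,
               stringsAsFactors = FALSE)
  }))

  per_round_ra <- NULL
  if (nrow(fb) && !is.null(session$behavior)) {
    key <- split(fb, list(fb$participant_id, fb$game, fb$round), drop = TRUE)
    per_round_ra <- do.call(rbind, lapply(key, function(f) {
      ra <- relative_attention(f, FEEDBACK_OWN_LABELS, FEEDBACK_OTHER_LABELS)
      data.frame(participant_id = f$participant_id[1], game = f$game[1],
                 round = f$round[1], ra = ra$ra, stringsAsFactors = FALSE)
    }))
    beh <- session$behavior
    beh$diff <- beh$contribution - (beh$sum - beh$contribution)
    per_round_ra <- merge(per_round_ra,
                          beh[, c("participant_id", "game", "round", "diff")],
                          by = c("participant_id", "game", "round"))
    rownames(per_round_ra) <- NULL
  }

  fits <- NULL; comparison <- NULL; w_ra <- NULL; ra_diff <- NULL
  if (!is.null(session$behavior) && nrow(session$behavior)) {
    hist <- histories_from_behavior(session$behavior)
    comparison <- compare_models(hist)
    fits <- comparison$per_individual[, c("participant_id", "w",
                                          "identifiable")]
    if (!is.null(attention)) {
      m <- merge(fits, attention, by = "participant_id")
      w_ra <- correlate_w_ra(m$w, m$ra)
    }
    if (!is.null(per_round_ra))
      ra_diff <- ra_vs_contribution_diff(per_round_ra$diff, per_round_ra$ra)
  }

  structure(list(fixations = fix, dwells = dwells, shares = shares,
                 correspondence = corr, attention = attention,
                 per_round_ra = per_round_ra, fits = fits,
                 comparison = comparison, w_ra = w_ra, ra_diff = ra_diff,
                 dispersion_px = dispersion_px,
                 min_duration_ms = min_duration_ms),
            class = "session_analysis")
}

#' @export
print.session_analysis <- function(x, ...) {
  cat("Session analysis\n")
  cat(sprintf("  %d fixations, %d dwells\n", nrow(x$fixations),
              nrow(x$dwells)))
  if (!is.null(x$correspondence))
    cat(sprintf("  last-fixation/click correspondence: %.3f\n",
                x$correspondence$rate))
  if (!is.null(x$comparison)) {
    cat("  grand MSDs:\n"); print(round(x$comparison$grand, 3))
  }
  if (!is.null(x$w_ra) && x$w_ra$defined)
    cat(sprintf("  r(w, ra) = %.3f (p = %.4g, n = %d)\n",
                x$w_ra$r, x$w_ra$p, x$w_ra$n))
  invisible(x)
}

#' Fraction of scripted fixations recovered by the analysis pipeline
#'
#' A scripted (ground-truth) fixation counts as recovered when some
#' detected fixation of the same participant carries the same AOI label
#' and overlaps it in time.
#'
#' @param session A `gazesync_session` (needs `truth`).
#' @param analysis The matching [analyze_session()] result.
#' @return Recovery rate in `[0, 1]`.
#' @export
truth_recovery_rate <- function(session, analysis) {
  tr <- session$truth
  fx <- analysis$fixations
  if (is.null(tr) || nrow(tr) == 0L) return(NA_real_)
  hit <- logical(nrow(tr))
  fkey <- paste(fx$participant_id, fx$aoi_label)
  tkey <- paste(tr$participant_id, tr$label)
  fsplit <- split(seq_len(nrow(fx)), fkey)
  for (g in unique(tkey)) {
    rows <- which(tkey == g)
    fi <- fsplit[[g]]
    if (is.null(fi)) next
    for (r in rows) {
      hit[r] <- any(fx$start_ms[fi] <= tr$offset_ms[r] &
                      fx$end_ms[fi] >= tr$onset_ms[r])
    }
  }
  mean(hit)
}
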