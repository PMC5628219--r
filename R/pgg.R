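#' Public goods game configuration
#'
#' A linear two-player public goods game: each player keeps
#' `endowment - c_i` and earns `mpcr * (c_i + c_j)` from the common pool.
#' With `0.5 < mpcr < 1` contributing is individually costly but
#' collectively beneficial — the social dilemma.
#'
#' @param endowment Points each player can contribute per round.
#' @param mpcr Marginal per-capita return of the pool, in (0.5, 1) for a
#'   two-player dilemma.
#' @param n_games,n_rounds Games per session and rounds per game.
#' @return A `game_config` list.
#' @export
game_config <- function(endowment = 20L, mpcr = 0.75, n_games = 3L,
                        n_rounds = 10L) {
  stop_if_not_scalar_number(endowment, "endowment", min = 1)
  stop_if_not_scalar_number(mpcr, "mpcr")
  if (mpcr <= 0.5 || mpcr >= 1)
    stop("`mpcr` must lie in (0.5, 1) for a two-player dilemma", call. = FALSE)
  structure(list(endowment = as.integer(endowment), mpcr = mpcr,
                 n_games = as.integer(n_games), n_rounds = as.integer(n_rounds)),
            class = "game_config")
}

#' Resolve one public goods round
#'
#' @param c_own,c_other Integer contributions in `[0, endowment]`.
#' @param cfg A [game_config()].
#' @return A `round_record` list: both contributions, their `sum` and
#'   `average`, and both payoffs
#'   (`payoff_i = endowment - c_i + mpcr * sum`). The payoff identity
#'   `payoff_own + payoff_other = 2*endowment + (2*mpcr - 1)*sum` holds on
#'   every round.
#' @export
play_round <- function(c_own, c_other, cfg = game_config()) {
  for (v in list(c_own = c_own, c_other = c_other)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v != round(v) ||
        v < 0 || v > cfg$endowment)
      stop("contributions must be integers in [0, ", cfg$endowment, "]",
           call. = FALSE)
  }
  s <- as.integer(c_own + c_other)
  structure(list(c_own = as.integer(c_own), c_other = as.integer(c_other),
                 sum = s, average = s / 2,
                 payoff_own = cfg$endowment - c_own + cfg$mpcr * s,
                 payoff_other = cfg$endowment - c_other + cfg$mpcr * s),
            class = "round_record")
}

aoi_row <- function(label, role, x, y, w, h, screen_id) {
  data.frame(label = label, role = role,
             x_px = as.integer(x), y_px = as.integer(y),
             w_px = as.integer(w), h_px = as.integer(h),
             screen_id = screen_id, stringsAsFactors = FALSE)
}

NUMERIC_ROLES <- c("own_points", "other_points", "sum", "average",
                   "numeric_other", "contribution_option")

#' Validate an AOI layout
#'
#' Checks that AOI rectangles (half-open, top-left anchored) are pairwise
#' non-overlapping and lie within the screen.
#'
#' @param aois AOI data frame
#'   (`label,role,x_px,y_px,w_px,h_px,screen_id`).
#' @param screen_w,screen_h Screen size in pixels.
#' @return `aois`, invisibly; errors on overlap or out-of-bounds AOIs.
#' @export
validate_layout <- function(aois, screen_w = 1920L, screen_h = 1080L) {
  if (any(aois$x_px < 0 | aois$y_px < 0 |
          aois$x_px + aois$w_px > screen_w |
          aois$y_px + aois$h_px > screen_h))
    stop("AOI outside screen bounds", call. = FALSE)
  n <- nrow(aois)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      if (aois$x_px[i] < aois$x_px[j] + aois$w_px[j] &&
          aois$x_px[j] < aois$x_px[i] + aois$w_px[i] &&
          aois$y_px[i] < aois$y_px[j] + aois$h_px[j] &&
          aois$y_px[j] < aois$y_px[i] + aois$h_px[i])
        stop("overlapping AOIs: ", aois$label[i], " / ", aois$label[j],
             call. = FALSE)
    }
  }
  invisible(aois)
}

#' Build the AOI layout of an experiment screen
#'
#' Two screens make up one round. The contribution screen shows the 21
#' possible contributions 0–20 as a 7x3 matrix of maximal non-overlapping
#' option AOIs (a 400x200 AOI cannot tile 21 options on a 1920 px screen,
#' so option cells default to 274x200). The feedback screen shows four
#' labeled rows — You, Person B, Sum, Average — each with two 400x200
#' numeric AOIs (current round and game total): 8 numeric AOIs plus 6
#' written-text AOIs (two column headers, four row labels).
#'
#' @param screen_id `"contribution"` or `"feedback"`.
#' @param screen_w,screen_h Screen resolution in pixels.
#' @param option_w,option_h Contribution option cell size.
#' @param numeric_w,numeric_h Feedback numeric AOI size.
#' @return A `screen_layout` list: `screen_id`, `screen_w`, `screen_h`,
#'   `aois` (validated AOI data frame).
#' @export
build_layout <- function(screen_id = c("contribution", "feedback"),
                         screen_w = 1920L, screen_h = 1080L,
                         option_w = 274L, option_h = 200L,
                         numeric_w = 400L, numeric_h = 200L) {
  screen_id <- match.arg(screen_id)
  if (screen_id == "contribution") {
    ncol <- 7L; nrowg <- 3L
    if (ncol * option_w > screen_w || nrowg * option_h > screen_h)
      stop("option cells do not fit the screen", call. = FALSE)
    x0 <- (screen_w - ncol * option_w) %/% 2L
    gap_y <- (screen_h - nrowg * option_h) %/% (nrowg + 1L)
    rows <- lapply(0:20, function(v) {
      r <- v %/% ncol; c <- v %% ncol
      aoi_row(as.character(v), "contribution_option",
              x0 + c * option_w, gap_y + r * (option_h + gap_y),
              option_w, option_h, screen_id)
    })
  } else {
    lbl_w <- 300L
    x_lbl <- 100L
    x_c1 <- x_lbl + lbl_w + 100L
    x_c2 <- x_c1 + numeric_w + 100L
    hdr_h <- 150L
    y_hdr <- 20L
    ys <- y_hdr + hdr_h + 40L + (0:3) * (numeric_h + 10L)
    roles <- c("own_points", "other_points", "sum", "average")
    names(roles) <- c("you", "personb", "sum", "avg")
    rows <- c(
      list(aoi_row("hdr_round", "text", x_c1, y_hdr, numeric_w, hdr_h, screen_id),
           aoi_row("hdr_total", "text", x_c2, y_hdr, numeric_w, hdr_h, screen_id)),
      unlist(lapply(seq_along(roles), function(i) {
        nm <- names(roles)[i]
        list(aoi_row(paste0("lbl_", nm), "text", x_lbl, ys[i], lbl_w, numeric_h,
                     screen_id),
             aoi_row(paste0(nm, "_round"), roles[[i]], x_c1, ys[i], numeric_w,
                     numeric_h, screen_id),
             aoi_row(paste0(nm, "_total"), roles[[i]], x_c2, ys[i], numeric_w,
                     numeric_h, screen_id))
      }), recursive = FALSE)
    )
  }
  aois <- do.call(rbind, rows)
  validate_layout(aois, screen_w, screen_h)
  structure(list(screen_id = screen_id, screen_w = as.integer(screen_w),
                 screen_h = as.integer(screen_h), aois = aois),
            class = "screen_layout")
}

#' Centers of a layout's AOIs
#' @param layout A `screen_layout`.
#' @return Data frame of `label`, `role`, `cx`, `cy`.
#' @keywords internal
aoi_centers <- function(layout) {
  a <- layout$aois
  data.frame(label = a$label, role = a$role,
             cx = a$x_px + a$w_px / 2, cy = a$y_px + a$h_px / 2,
             stringsAsFactors = FALSE)
}
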