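empty_fixations <- function() {
  data.frame(participant_id = character(0), start_ms = integer(0),
             end_ms = integer(0), duration_ms = integer(0),
             cx_px = numeric(0), cy_px = numeric(0), n_samples = integer(0),
             stringsAsFactors = FALSE)
}

# greedy dispersion-threshold pass over one gap-free run of valid samples
idt_run <- function(t, x, y, dispersion_px, min_duration_ms) {
  n <- length(t)
  out <- vector("list", 8L); nout <- 0L
  i <- 1L
  while (i <= n) {
    j <- i
    xmin <- xmax <- x[i]; ymin <- ymax <- y[i]
    while (j < n) {
      nxmin <- min(xmin, x[j + 1L]); nxmax <- max(xmax, x[j + 1L])
      nymin <- min(ymin, y[j + 1L]); nymax <- max(ymax, y[j + 1L])
      if ((nxmax - nxmin) + (nymax - nymin) <= dispersion_px) {
        j <- j + 1L
        xmin <- nxmin; xmax <- nxmax; ymin <- nymin; ymax <- nymax
      } else break
    }
    if (t[j] - t[i] >= min_duration_ms) {
      nout <- nout + 1L
      if (nout > length(out)) out <- c(out, vector("list", length(out)))
      out[[nout]] <- c(t[i], t[j], mean(x[i:j]), mean(y[i:j]), j - i + 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  out[seq_len(nout)]
}

#' Detect fixations with the dispersion-threshold (I-DT) algorithm
#'
#' Grows a sample window left to right while its dispersion
#' `(max(x) - min(x)) + (max(y) - min(y))` stays at or under
#' `dispersion_px`; when the window can grow no further and spans at least
#' `min_duration_ms`, it is emitted as a fixation with centroid at the mean
#' of its member samples, and scanning resumes after it (greedy,
#' non-overlapping). Invalid samples break candidate windows.
#'
#' Defaults are the common literature settings: a dispersion of ~1° of
#' visual angle (38 px at the package's default viewing geometry) and a
#' 100 ms minimum duration.
#'
#' @param samples Gaze-sample data frame, time-ordered within participant.
#' @param dispersion_px Maximum window dispersion in pixels (>= 0).
#' @param min_duration_ms Minimum fixation duration in ms (>= 0).
#' @return Fixation data frame: `participant_id`, `start_ms`, `end_ms`,
#'   `duration_ms`, `cx_px`, `cy_px`, `n_samples`, ordered and
#'   non-overlapping within participant.
#' @export
detect_fixations_idt <- function(samples, dispersion_px = 38,
                                 min_duration_ms = 100) {
  stop_if_not_scalar_number(dispersion_px, "dispersion_px", min = 0)
  stop_if_not_scalar_number(min_duration_ms, "min_duration_ms", min = 0)
  if (nrow(samples) == 0L) return(empty_fixations())
  check_sorted_per_participant(samples, "gaze")
  res <- lapply(split(samples, samples$participant_id), function(df) {
    keep <- df$valid & !is.na(df$x_px) & !is.na(df$y_px)
    if (!any(keep)) return(NULL)
    runs <- rle(keep)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    fx <- list()
    for (r in which(runs$values)) {
      idx <- starts[r]:ends[r]
      fx <- c(fx, idt_run(df$t_ms[idx], df$x_px[idx], df$y_px[idx],
                          dispersion_px, min_duration_ms))
    }
    if (!length(fx)) return(NULL)
    m <- do.call(rbind, fx)
    data.frame(participant_id = df$participant_id[1],
               start_ms = as.integer(m[, 1]), end_ms = as.integer(m[, 2]),
               duration_ms = as.integer(m[, 2] - m[, 1]),
               cx_px = m[, 3], cy_px = m[, 4], n_samples = as.integer(m[, 5]),
               stringsAsFactors = FALSE)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) return(empty_fixations())
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Assign fixations to areas of interest
#'
#' Labels each fixation with the unique AOI whose half-open rectangle
#' `[x, x + w) x [y, y + h)` contains its centroid, or `NA` when none does.
#'
#' @param fixations Fixation data frame (needs `cx_px`, `cy_px`).
#' @param layout A [build_layout()] result, or an AOI data frame.
#' @return `fixations` with `aoi_label` and `aoi_role` columns added.
#' @export
assign_aois <- function(fixations, layout) {
  aois <- if (inherits(layout, "screen_layout")) layout$aois else layout
  validate_layout(aois,
                  screen_w = max(aois$x_px + aois$w_px, 1920L),
                  screen_h = max(aois$y_px + aois$h_px, 1080L))
  lab <- rep(NA_character_, nrow(fixations))
  role <- rep(NA_character_, nrow(fixations))
  for (k in seq_len(nrow(aois))) {
    inside <- fixations$cx_px >= aois$x_px[k] &
      fixations$cx_px < aois$x_px[k] + aois$w_px[k] &
      fixations$cy_px >= aois$y_px[k] &
      fixations$cy_px < aois$y_px[k] + aois$h_px[k]
    lab[inside] <- aois$label[k]
    role[inside] <- aois$role[k]
  }
  fixations$aoi_label <- lab
  fixations$aoi_role <- role
  fixations
}

#' Collapse labeled fixations into dwells
#'
#' A dwell is one visit to an AOI from entry to exit: a maximal run of
#' consecutive same-AOI fixations. Its dwell time is the sum of the member
#' fixation durations. Unlabeled fixations terminate runs and produce no
#' dwell.
#'
#' @param fixations Labeled, time-ordered fixation data frame (needs
#'   `aoi_label`, `start_ms`, `end_ms`, `duration_ms`).
#' @return Dwell data frame: `participant_id`, `aoi_label`, `entry_ms`,
#'   `exit_ms`, `dwell_ms`, `n_fixations`.
#' @export
compute_dwells <- function(fixations) {
  out <- lapply(split(fixations, fixations$participant_id), function(df) {
    df <- df[order(df$start_ms), , drop = FALSE]
    lab <- df$aoi_label
    key <- ifelse(is.na(lab), paste0(".none.", seq_along(lab)), lab)
    runs <- rle(key)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- !startsWith(runs$values, ".none.")
    if (!any(keep)) return(NULL)
    data.frame(
      participant_id = df$participant_id[1],
      aoi_label = runs$values[keep],
      entry_ms = df$start_ms[starts[keep]],
      exit_ms = df$end_ms[ends[keep]],
      dwell_ms = vapply(which(keep), function(r)
        sum(df$duration_ms[starts[r]:ends[r]]), numeric(1)),
      n_fixations = runs$lengths[keep],
      stringsAsFactors = FALSE
    )
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(participant_id = character(0), aoi_label = character(0),
                      entry_ms = integer(0), exit_ms = integer(0),
                      dwell_ms = numeric(0), n_fixations = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Correspondence between the last AOI fixation and the clicked option
#'
#' For each click, finds that participant's latest fixation starting at or
#' before the click that carries an AOI label, and scores a match when its
#' label equals the clicked AOI. Clicks with no prior labeled fixation are
#' counted as non-matches and flagged.
#'
#' @param fixations Labeled fixation data frame.
#' @param clicks Data frame with `participant_id`, `t_ms`, `clicked_label`.
#' @return A list: `per_click` (clicks with `last_label`, `match`,
#'   `no_prior_fixation`) and `rate` (matches / clicks).
#' @export
last_fixation_correspondence <- function(fixations, clicks) {
  n <- nrow(clicks)
  last_label <- rep(NA_character_, n)
  flag <- rep(FALSE, n)
  for (i in seq_len(n)) {
    f <- fixations[fixations$participant_id == clicks$participant_id[i] &
                     fixations$start_ms <= clicks$t_ms[i] &
                     !is.na(fixations$aoi_label), , drop = FALSE]
    if (nrow(f) == 0L) flag[i] <- TRUE
    else last_label[i] <- f$aoi_label[which.max(f$start_ms)]
  }
  match <- !is.na(last_label) & last_label == clicks$clicked_label
  per_click <- cbind(clicks,
                     data.frame(last_label = last_label, match = match,
                                no_prior_fixation = flag))
  list(per_click = per_click,
       rate = if (n > 0) sum(match) / n else NA_real_)
}

#' Fixation shares by AOI role
#'
#' Splits fixations into numeric-AOI, text-AOI and non-AOI classes and
#' reports each class's share of all fixations (shares sum to 1 on
#' non-empty input), plus per-AOI fixation counts.
#'
#' @param fixations Labeled fixation data frame (needs `aoi_role`).
#' @return A list: `shares` (named numeric: `numeric`, `text`, `none`),
#'   `counts` (per-AOI fixation counts), `n_fixations`, `empty` flag.
#' @export
aoi_share_report <- function(fixations) {
  n <- nrow(fixations)
  if (n == 0L)
    return(list(shares = c(numeric = 0, text = 0, none = 0),
                counts = data.frame(aoi_label = character(0), n = integer(0)),
                n_fixations = 0L, empty = TRUE))
  cls <- ifelse(is.na(fixations$aoi_role), "none",
                ifelse(fixations$aoi_role %in% NUMERIC_ROLES, "numeric", "text"))
  shares <- c(numeric = sum(cls == "numeric"), text = sum(cls == "text"),
              none = sum(cls == "none")) / n
  tab <- table(fixations$aoi_label, useNA = "no")
  list(shares = shares,
       counts = data.frame(aoi_label = names(tab), n = as.integer(tab),
                           stringsAsFactors = FALSE),
       n_fixations = n, empty = FALSE)
}

#' Relative attention to own versus other's payoff information
#'
#' The attention ratio `ra = n_own / (n_own + n_other)`, where the counts
#' are fixations on the participant's own payoff AOIs versus the other
#' player's. `weight = "duration"` substitutes summed fixation durations
#' for counts. Undefined (flagged, `ra = NA`) when both totals are zero.
#'
#' @param fixations Labeled fixation data frame.
#' @param own_labels,other_labels Disjoint character vectors of AOI labels.
#' @param weight `"count"` (default) or `"duration"`.
#' @return An `attention_summary` list: `n_fix_own`, `n_fix_other`, `ra`,
#'   `defined`.
#' @export
relative_attention <- function(fixations, own_labels, other_labels,
                               weight = c("count", "duration")) {
  weight <- match.arg(weight)
  if (length(intersect(own_labels, other_labels)))
    stop("own and other AOI label sets must be disjoint", call. = FALSE)
  w_of <- function(labs) {
    sel <- !is.na(fixations$aoi_label) & fixations$aoi_label %in% labs
    if (weight == "count") sum(sel) else sum(fixations$duration_ms[sel])
  }
  own <- w_of(own_labels); oth <- w_of(other_labels)
  structure(list(n_fix_own = own, n_fix_other = oth,
                 ra = if (own + oth > 0) own / (own + oth) else NA_real_,
                 defined = own + oth > 0),
            class = "attention_summary")
}
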