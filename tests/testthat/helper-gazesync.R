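# Shared fixtures and independent oracles for the test suite.

## ---- independent I-DT oracle -----------------------------------------------
# Recomputes, for every window start, the maximal window satisfying the
# dispersion criterion from scratch (vectorized cummax/cummin over the
# slice), then applies the same greedy emit rule. Shares no code with the
# incremental detector.
oracle_idt <- function(samples, dispersion_px, min_duration_ms) {
  per_participant <- lapply(split(samples, samples$participant_id), function(df) {
    keep <- df$valid & !is.na(df$x_px) & !is.na(df$y_px)
    out <- list()
    i0 <- 1L
    n_all <- nrow(df)
    while (i0 <= n_all) {
      if (!keep[i0]) { i0 <- i0 + 1L; next }
      j0 <- i0
      while (j0 < n_all && keep[j0 + 1L]) j0 <- j0 + 1L
      t <- df$t_ms[i0:j0]; x <- df$x_px[i0:j0]; y <- df$y_px[i0:j0]
      n <- length(t); i <- 1L
      while (i <= n) {
        slice <- i:n
        disp <- (cummax(x[slice]) - cummin(x[slice])) +
          (cummax(y[slice]) - cummin(y[slice]))
        viol <- which(disp > dispersion_px)
        j <- if (length(viol)) i + viol[1] - 2L else n
        if (t[j] - t[i] >= min_duration_ms) {
          out[[length(out) + 1L]] <- data.frame(
            participant_id = df$participant_id[1],
            start_ms = t[i], end_ms = t[j], duration_ms = t[j] - t[i],
            cx_px = mean(x[i:j]), cy_px = mean(y[i:j]),
            n_samples = j - i + 1L, stringsAsFactors = FALSE)
          i <- j + 1L
        } else i <- i + 1L
      }
      i0 <- j0 + 1L
    }
    if (length(out)) do.call(rbind, out) else NULL
  })
  per_participant <- per_participant[!vapply(per_participant, is.null, logical(1))]
  if (!length(per_participant)) return(NULL)
  res <- do.call(rbind, per_participant)
  rownames(res) <- NULL
  res
}

# random gaze stream mixing stationary clusters, drift and dropouts
random_stream <- function(n, seed, participant_id = "p01") {
  set.seed(seed)
  t <- as.integer(cumsum(c(0L, rep(17L, n - 1L))))
  k <- max(1L, rpois(1, n / 40))
  centers <- matrix(runif(2 * k, 0, 1900), ncol = 2)
  idx <- sort(sample(seq_len(k), n, replace = TRUE))
  jitter_sd <- runif(1, 1, 30)
  data.frame(participant_id = participant_id, t_ms = t,
             x_px = centers[idx, 1] + rnorm(n, 0, jitter_sd),
             y_px = centers[idx, 2] + rnorm(n, 0, jitter_sd),
             pupil = 4, valid = runif(n) > 0.05,
             stringsAsFactors = FALSE)
}

## ---- message fuzzing --------------------------------------------------------
random_message <- function() {
  body_n <- sample(0:4, 1)
  body <- list()
  if (body_n > 0) {
    vals <- replicate(body_n, switch(sample(3, 1),
      paste(sample(letters, sample(1:8, 1), replace = TRUE), collapse = ""),
      round(runif(sample(1:3, 1), -1e4, 1e4), 3),
      sample(c(TRUE, FALSE), 1)), simplify = FALSE)
    names(vals) <- paste0("k", seq_len(body_n))
    body <- vals
  }
  wire_message(sample(gazesync:::MSG_TYPES, 1),
               paste0("p", sample(99, 1)),
               sample(0:1e6, 1), body)
}

## ---- agents and sessions ----------------------------------------------------
# default calibration quality is tight so tests that are not about the
# calibration policy never lose participants to it
make_agents <- function(n, w = NULL, seed = 1, cal_quality_mean = 0.35,
                        cal_quality_sd = 0.05, ...) {
  set.seed(seed)
  if (is.null(w)) w <- runif(n)
  lapply(seq_len(n), function(k)
    agent_spec(sprintf("a%02d", k), true_w = w[k],
               cal_quality_mean = cal_quality_mean,
               cal_quality_sd = cal_quality_sd, ...))
}

small_session <- function(n = 4, n_games = 2, n_rounds = 4, seed = 11, ...) {
  generate_session(
    session_config(n_participants = n, n_games = n_games, n_rounds = n_rounds,
                   seed = seed, ...),
    make_agents(n, seed = seed), seed = seed)
}

# simulate one focal matching agent against an erratic probe partner and
# return the focal agent's history
probe_history <- function(true_w, noise_sd, seed, n_games = 3, n_rounds = 10) {
  focal <- agent_spec("focal", true_w = true_w, behavior_noise_sd = noise_sd)
  probe <- agent_spec("probe", strategy = "erratic")
  pair_member_history(
    simulate_contributions(focal, probe, n_games, n_rounds, seed = seed), "i")
}

# grid-search oracle for the matching weight (0.001 grid)
grid_fit_w <- function(history, step = 0.001) {
  grid <- seq(0, 1, by = step)
  lh <- gazesync:::lagged_history(history)
  if (is.null(lh)) return(NA_real_)
  errs <- vapply(grid, function(w)
    mean((w * lh$own_lag + (1 - w) * lh$other_lag - lh$own)^2), numeric(1))
  grid[which.min(errs)]
}
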