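mk_samples <- function(t, x, y, valid = TRUE, id = "p01")
  data.frame(participant_id = id, t_ms = as.integer(t), x_px = x, y_px = y,
             pupil = 4, valid = valid, stringsAsFactors = FALSE)

test_that("I-DT handles the canonical degenerate and forced cases", {
  # 60 identical samples over ~1 s -> one fixation at the sample point
  t <- seq(0, by = 1000 / 60, length.out = 60)
  s <- mk_samples(t, rep(960, 60), rep(540, 60))
  fx <- detect_fixations_idt(s, 38, 100)
  expect_equal(nrow(fx), 1)
  expect_equal(fx$cx_px, 960)
  expect_equal(fx$cy_px, 540)
  expect_gt(fx$duration_ms, 950)

  # two stationary clusters separated by a jump beyond dispersion -> two
  s2 <- mk_samples(seq(0, by = 17, length.out = 40),
                   c(rep(100, 18), 300, 500, rep(700, 20)),
                   rep(100, 40))
  fx2 <- detect_fixations_idt(s2, 38, 100)
  expect_equal(nrow(fx2), 2)
  expect_equal(fx2$cx_px, c(100, 700))

  expect_equal(nrow(detect_fixations_idt(gazesync:::empty_gaze())), 0)
  expect_error(detect_fixations_idt(s, -1, 100), "dispersion")

  # invalid samples break candidate windows
  s3 <- s
  s3$valid[30] <- FALSE
  fx3 <- detect_fixations_idt(s3, 38, 100)
  expect_equal(nrow(fx3), 2)
})

test_that("I-DT agrees with the brute-force window-enumeration oracle", {
  for (k in 1:12) {
    s <- random_stream(sample(100:800, 1), seed = 7000 + k)
    for (disp in c(20, 60, 150)) {
      got <- detect_fixations_idt(s, disp, 100)
      want <- oracle_idt(s, disp, 100)
      if (is.null(want)) expect_equal(nrow(got), 0)
      else expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("fixation count is non-increasing in the minimum duration", {
  s <- random_stream(1200, seed = 555)
  counts <- vapply(c(0, 50, 100, 200, 400), function(md)
    nrow(detect_fixations_idt(s, 60, md)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("AOI assignment respects the half-open rectangle convention", {
  layout <- build_layout("feedback")
  a <- layout$aois[layout$aois$label == "you_round", ]
  fx <- data.frame(participant_id = "p01", start_ms = c(0, 100, 200, 300),
                   end_ms = c(50, 150, 250, 350), duration_ms = 50,
                   cx_px = c(a$x_px, a$x_px + a$w_px, a$x_px + 1, -5),
                   cy_px = c(a$y_px, a$y_px + a$h_px, a$y_px + 1, -5),
                   n_samples = 3)
  got <- assign_aois(fx, layout)
  expect_equal(got$aoi_label, c("you_round", NA, "you_round", NA))

  # containment oracle on random centroids
  set.seed(31)
  n <- 500
  rnd <- data.frame(participant_id = "p01", start_ms = 1:n, end_ms = 1:n + 10,
                    duration_ms = 10, cx_px = runif(n, -50, 1970),
                    cy_px = runif(n, -50, 1130), n_samples = 1)
  got <- assign_aois(rnd, layout)
  oracle <- vapply(seq_len(n), function(i) {
    aa <- layout$aois
    hit <- which(rnd$cx_px[i] >= aa$x_px & rnd$cx_px[i] < aa$x_px + aa$w_px &
                   rnd$cy_px[i] >= aa$y_px & rnd$cy_px[i] < aa$y_px + aa$h_px)
    if (length(hit)) aa$label[hit] else NA_character_
  }, character(1))
  expect_identical(got$aoi_label, oracle)

  overlapping <- rbind(
    gazesync:::aoi_row("a", "text", 0, 0, 100, 100, "s"),
    gazesync:::aoi_row("b", "text", 50, 50, 100, 100, "s"))
  expect_error(assign_aois(rnd, overlapping), "overlap")
})

test_that("dwells collapse same-AOI runs and conserve fixation time", {
  fx <- data.frame(participant_id = "p01",
                   start_ms = c(0, 300, 700, 1100),
                   end_ms = c(200, 600, 1000, 1400),
                   duration_ms = c(200, 300, 300, 300),
                   cx_px = 0, cy_px = 0, n_samples = 5,
                   aoi_label = c("A", "A", "B", NA),
                   stringsAsFactors = FALSE)
  d <- compute_dwells(fx)
  expect_equal(d$aoi_label, c("A", "B"))
  expect_equal(d$n_fixations, c(2, 1))
  expect_equal(d$dwell_ms, c(500, 300))
  expect_equal(d$entry_ms[1], 0)
  expect_equal(d$exit_ms[1], 600)

  # conservation on a generated session: per AOI, total dwell time equals
  # total fixation time
  s <- small_session(n = 2, n_games = 1, n_rounds = 3, seed = 41)
  an <- analyze_session(s)
  fx_tot <- tapply(an$fixations$duration_ms[!is.na(an$fixations$aoi_label)],
                   paste(an$fixations$participant_id,
                         an$fixations$aoi_label)[!is.na(an$fixations$aoi_label)],
                   sum)
  dw_tot <- tapply(an$dwells$dwell_ms,
                   paste(an$dwells$participant_id, an$dwells$aoi_label), sum)
  expect_equal(dw_tot[names(fx_tot)], fx_tot)
})

test_that("last-fixation/click correspondence scores matches and flags orphans", {
  fx <- data.frame(participant_id = "p01", start_ms = c(0, 400, 900),
                   end_ms = c(300, 800, 1200), duration_ms = c(300, 400, 300),
                   cx_px = 0, cy_px = 0, n_samples = 5,
                   aoi_label = c("11", NA, "12"), stringsAsFactors = FALSE)
  hit <- last_fixation_correspondence(
    fx, data.frame(participant_id = "p01", t_ms = 1300, clicked_label = "12"))
  expect_equal(hit$rate, 1)
  miss <- last_fixation_correspondence(
    fx, data.frame(participant_id = "p01", t_ms = 700, clicked_label = "12"))
  expect_equal(miss$rate, 0)
  expect_equal(miss$per_click$last_label, "11")
  orphan <- last_fixation_correspondence(
    fx, data.frame(participant_id = "p99", t_ms = 100, clicked_label = "3"))
  expect_true(orphan$per_click$no_prior_fixation)
  expect_equal(orphan$rate, 0)
})

test_that("AOI-role shares partition all fixations", {
  fx <- data.frame(participant_id = "p01", start_ms = 1:10, end_ms = 2:11,
                   duration_ms = 1, cx_px = 0, cy_px = 0, n_samples = 1,
                   aoi_label = c(rep("you_round", 4), rep("lbl_you", 3),
                                 rep(NA, 3)),
                   aoi_role = c(rep("own_points", 4), rep("text", 3),
                                rep(NA, 3)),
                   stringsAsFactors = FALSE)
  rep_ <- aoi_share_report(fx)
  expect_equal(unname(rep_$shares), c(0.4, 0.3, 0.3))
  expect_equal(sum(rep_$shares), 1)

  all_num <- aoi_share_report(fx[1:4, ])
  expect_equal(unname(all_num$shares["numeric"]), 1)

  none <- aoi_share_report(fx[0, ])
  expect_true(none$empty)
  expect_equal(unname(none$shares), c(0, 0, 0))
})

test_that("relative attention is the own-share of own+other fixations", {
  mk_fx <- function(n_own, n_other) {
    n <- n_own + n_other
    data.frame(
      participant_id = rep("p01", n), start_ms = seq_len(n),
      end_ms = seq_len(n) + 100, duration_ms = rep(100, n),
      cx_px = rep(0, n), cy_px = rep(0, n), n_samples = rep(1, n),
      aoi_label = c(rep("you_round", n_own), rep("personb_round", n_other)),
      stringsAsFactors = FALSE)
  }
  expect_equal(relative_attention(mk_fx(10, 10), "you_round",
                                  "personb_round")$ra, 0.5)
  expect_equal(relative_attention(mk_fx(30, 10), "you_round",
                                  "personb_round")$ra, 0.75)
  expect_equal(relative_attention(mk_fx(0, 7), "you_round",
                                  "personb_round")$ra, 0)
  undef <- relative_attention(mk_fx(0, 0), "you_round", "personb_round")
  expect_false(undef$defined)
  expect_true(is.na(undef$ra))
  expect_error(relative_attention(mk_fx(1, 1), "A", "A"), "disjoint")

  # duration weighting changes the ratio when durations differ
  fx <- mk_fx(1, 1)
  fx$duration_ms <- c(300, 100)
  expect_equal(relative_attention(fx, "you_round", "personb_round",
                                  weight = "duration")$ra, 0.75)
})
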