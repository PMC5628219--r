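mk_hist <- function(own, other, game = 1)
  data.frame(game = game, round = seq_along(own), own = own, other = other)

test_that("matching predictions are the stated weighted average of lags", {
  h <- mk_hist(c(12, 16), c(20, 10))
  expect_equal(predict_matching(h, 0.5)$pred[1], 16)  # (12 + 20) / 2
  expect_equal(predict_matching(h, 1)$pred, h$own[-2])
  expect_equal(predict_matching(h, 0)$pred, h$other[-2])

  set.seed(2)
  h2 <- mk_hist(sample(0:20, 10, TRUE), sample(0:20, 10, TRUE))
  p <- predict_matching(h2, 0.3)
  expect_true(all(p$pred >= 0 & p$pred <= 20))  # convex combination
  expect_equal(p$pred, 0.3 * h2$own[-10] + 0.7 * h2$other[-10])
  expect_null(predict_matching(mk_hist(12, 20), 0.5))  # one round: nothing
})

test_that("conditional cooperation strategies predict as defined", {
  h <- mk_hist(c(5, 9, 14), c(20, 15, 12))
  expect_equal(predict_cc_naive(h)$pred, c(20, 15))
  expect_equal(predict_cc_actual(h)$pred, c(15, 12))
  expect_equal(predict_cc_naive(h)$pred, predict_matching(h, 0)$pred)
  const <- mk_hist(c(5, 9, 14), c(7, 7, 7))
  expect_equal(predict_cc_naive(const)$pred, c(7, 7))
  expect_equal(predict_cc_naive(const)$pred, predict_cc_actual(const)$pred)
})

test_that("msd matches an independent recomputation", {
  expect_equal(msd(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(msd(c(3, 5), c(1, 3)), 4)  # constant error of 2
  set.seed(3)
  p <- runif(40, 0, 20); a <- runif(40, 0, 20)
  expect_equal(msd(p, a), sum((p - a)^2) / 40)
  und <- msd(numeric(0), numeric(0))
  expect_true(is.na(und) && isTRUE(attr(und, "undefined")))
  expect_error(msd(1:3, 1:2), "aligned")
})

test_that("the closed-form fit recovers a noise-free generating weight exactly", {
  w_true <- 0.7
  own <- other <- numeric(10)
  own[1] <- 12; other[1] <- 20
  for (t in 2:10) {
    own[t] <- w_true * own[t - 1] + (1 - w_true) * other[t - 1]
    other[t] <- 0.4 * other[t - 1] + 0.6 * own[t - 1]
  }
  fit <- fit_w(mk_hist(own, other))
  expect_true(fit$identifiable)
  expect_equal(fit$w, 0.7, tolerance = 1e-9)

  # own == other throughout: unidentifiable and flagged
  flat <- fit_w(mk_hist(rep(12, 6), rep(12, 6)))
  expect_false(flat$identifiable)
  expect_true(is.na(flat$w))
})

test_that("the closed form agrees with a 0.001-step grid search on noisy agents", {
  set.seed(17)
  for (k in 1:40) {
    h <- probe_history(runif(1), noise_sd = 2, seed = 9000 + k)
    w_cf <- fit_w(h)$w
    w_grid <- grid_fit_w(h)
    expect_lt(abs(w_cf - w_grid), 0.001 + 1e-12)
  }
})

test_that("the matching_model object behaves like a classed R model fit", {
  h <- probe_history(0.6, noise_sd = 1, seed = 404)
  m <- matching_model(h)
  expect_s3_class(m, "matching_model")
  expect_named(coef(m), "w")
  expect_equal(length(residuals(m)), nrow(m$pred))
  expect_equal(fitted(m) + residuals(m), m$pred$own)
  expect_equal(m$msd, mean(residuals(m)^2))
  expect_output(print(m), "w = ")
  expect_output(print(summary(m)), "MSD")

  m05 <- matching_model(h, w = 0.5)
  expect_false(m05$fitted_w)
  expect_gte(m05$msd, m$msd)  # fitted w minimizes the in-sample MSD

  sim <- simulate(m, nsim = 2, seed = 1, n_rounds = 8)
  expect_length(sim, 2)
  expect_true(all(sim[[1]]$own >= 0 & sim[[1]]$own <= 20))
})

test_that("model comparison ranks a copy-other population as pure actual-belief CC", {
  set.seed(5)
  hists <- lapply(1:6, function(k) {
    other <- sample(0:20, 8, TRUE)
    mk_hist(own = other, other = other)  # perfect same-round copier
  })
  names(hists) <- paste0("p", 1:6)
  cmp <- compare_models(hists)
  expect_equal(unname(cmp$grand["msd_cc_actual"]), 0)
  # copiers make w unidentifiable (lags never differ) and are flagged
  expect_true(all(!cmp$per_individual$identifiable))

  # on identifiable noisy agents the fitted weight never loses to w = 0.5
  hists2 <- lapply(1:8, function(k) probe_history(runif(1), 2, 300 + k))
  names(hists2) <- paste0("q", 1:8)
  cmp2 <- compare_models(hists2)
  expect_true(all(cmp2$per_individual$msd_matching_fitted <=
                    cmp2$per_individual$msd_matching_w05 + 1e-12))
})

test_that("the w-ra correlation and its degenerate cases behave", {
  w <- seq(0.1, 0.9, length.out = 9)
  perfect <- correlate_w_ra(w, w)
  expect_equal(perfect$r, 1)
  expect_lt(perfect$p, 1e-6)
  expect_false(correlate_w_ra(w, rep(0.5, 9))$defined)
  expect_false(correlate_w_ra(w[1:2], w[1:2])$defined)
  with_na <- correlate_w_ra(c(w, NA), c(w, 0.5))
  expect_equal(with_na$n, 9)
})

test_that("the ra-on-difference slope is exact on constructed data and flags degenerates", {
  diff <- -10:10
  ra <- 0.5 - 0.01 * diff
  fit <- ra_vs_contribution_diff(diff, ra)
  expect_equal(fit$slope, -0.01, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.5, tolerance = 1e-12)
  expect_false(ra_vs_contribution_diff(rep(3, 10), runif(10))$defined)

  # negative coupling with noise recovers a negative slope almost surely
  set.seed(19)
  neg <- replicate(100, {
    d <- sample(-15:15, 60, TRUE)
    r <- clip(0.5 - 0.012 * d + rnorm(60, 0, 0.08), 0, 1)
    ra_vs_contribution_diff(d, r)$slope < 0
  })
  expect_gte(sum(neg), 95)
})
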