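#' Contribution models
#'
#' Round-by-round models of how a player chooses the next contribution in
#' an iterated two-player public goods game, given the pair's history:
#'
#' * the *matching model*: the next contribution is a weighted average of
#'   the player's own and the partner's previous contributions,
#'   `C[t] = w * own[t-1] + (1 - w) * other[t-1]`, with `w` in `[0, 1]`
#'   interpretable as the relative attention given to one's own payoffs;
#' * *conditional cooperation with naive beliefs*: match the partner's last
#'   observed contribution, `C[t] = other[t-1]` (the matching model at
#'   `w = 0`);
#' * *conditional cooperation with actual beliefs*: match the partner's
#'   same-round contribution, `C[t] = other[t]`.
#'
#' Models are scored by the mean squared deviation (MSD) from observed
#' contributions over all predicted rounds (`t >= 2` within each game,
#' games pooled per individual). Predictions are real-valued; no rounding
#' is applied before scoring.
#'
#' @name contribution_models
NULL

check_history <- function(history) {
  need <- c("game", "round", "own", "other")
  if (!all(need %in% names(history)))
    stop("history needs columns ", paste(need, collapse = ", "), call. = FALSE)
  history <- history[order(history$game, history$round), , drop = FALSE]
  if (any(history$own < 0 | history$own > 20 | history$other < 0 |
          history$other > 20, na.rm = TRUE))
    stop("contributions must lie in [0, 20]", call. = FALSE)
  history
}

# per-game lagged view: rows for t >= 2 with own/other lags and actuals
lagged_history <- function(history) {
  history <- check_history(history)
  out <- lapply(split(history, history$game), function(g) {
    n <- nrow(g)
    if (n < 2L) return(NULL)
    data.frame(game = g$game[-1], round = g$round[-1],
               own_lag = g$own[-n], other_lag = g$other[-n],
               own = g$own[-1], other = g$other[-1])
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Matching-model predictions
#'
#' @param history Data frame with columns `game`, `round`, `own`, `other`
#'   (integer contributions in `[0, 20]`).
#' @param w Weight on the player's own previous contribution, in `[0, 1]`.
#' @return Data frame of predicted rounds (`t >= 2` per game) with a
#'   `pred` column; round 1 of each game has no prediction.
#' @export
predict_matching <- function(history, w) {
  stop_if_not_scalar_number(w, "w", min = 0, max = 1)
  lh <- lagged_history(history)
  if (is.null(lh)) return(NULL)
  lh$pred <- w * lh$own_lag + (1 - w) * lh$other_lag
  lh
}

#' Conditional cooperation with naive beliefs
#' @inheritParams predict_matching
#' @return As [predict_matching()]: `pred = other[t-1]`.
#' @export
predict_cc_naive <- function(history) {
  lh <- lagged_history(history)
  if (is.null(lh)) return(NULL)
  lh$pred <- lh$other_lag
  lh
}

#' Conditional cooperation with actual beliefs
#' @inheritParams predict_matching
#' @return As [predict_matching()]: `pred = other[t]` (scored on the same
#'   `t >= 2` rounds as the other models, for identical denominators).
#' @export
predict_cc_actual <- function(history) {
  lh <- lagged_history(history)
  if (is.null(lh)) return(NULL)
  lh$pred <- lh$other
  lh
}

#' Mean squared deviation between predictions and behavior
#'
#' @param pred,actual Aligned numeric vectors over the predicted rounds.
#' @return Mean of squared errors; `NA` (flagged by attribute
#'   `"undefined"`) when there are no predicted rounds.
#' @export
msd <- function(pred, actual) {
  if (length(pred) != length(actual))
    stop("`pred` and `actual` must be aligned", call. = FALSE)
  if (length(pred) == 0L)
    return(structure(NA_real_, undefined = TRUE))
  mean((pred - actual)^2)
}

#' Closed-form least-squares estimate of the matching weight
#'
#' Minimizes the MSD of the matching model over `w` in `[0, 1]`. Writing
#' `d[t] = own[t-1] - other[t-1]` and `e[t] = own[t] - other[t-1]`, the
#' unconstrained minimizer is `w* = sum(e * d) / sum(d^2)`, clipped to
#' `[0, 1]`. When the lagged contributions never differ (`d == 0`
#' throughout), `w` is unidentifiable and the result is flagged.
#'
#' @inheritParams predict_matching
#' @return A `matching_params` list: `w` (NA when unidentifiable),
#'   `identifiable`, `n_pred` (number of predicted rounds).
#' @export
fit_w <- function(history) {
  lh <- lagged_history(history)
  if (is.null(lh))
    return(structure(list(w = NA_real_, identifiable = FALSE, n_pred = 0L),
                     class = "matching_params"))
  d <- lh$own_lag - lh$other_lag
  e <- lh$own - lh$other_lag
  if (all(d == 0))
    return(structure(list(w = NA_real_, identifiable = FALSE,
                          n_pred = nrow(lh)), class = "matching_params"))
  w <- clip(sum(e * d) / sum(d^2), 0, 1)
  structure(list(w = w, identifiable = TRUE, n_pred = nrow(lh)),
            class = "matching_params")
}

#' Fit the matching model to one individual's history
#'
#' The modelling front end over [fit_w()]: estimates the attention weight
#' `w` by least squares and packages predictions, residuals and the MSD as
#' a classed model object.
#'
#' @param history Data frame with columns `game`, `round`, `own`, `other`.
#' @param w Optional fixed weight; when supplied no fitting is done (e.g.
#'   `w = 0.5` gives the plain averaging model).
#' @return An object of class `matching_model` with components `w`,
#'   `fitted_w` (logical), `identifiable`, `history`, `pred` (predicted
#'   rounds), `msd`.
#' @seealso [compare_models()], [predict_matching()]
#' @export
#' @examples
#' h <- data.frame(game = 1, round = 1:5,
#'                 own = c(12, 15, 14, 15, 15), other = c(20, 14, 16, 15, 15))
#' m <- matching_model(h)
#' coef(m)
#' summary(m)
matching_model <- function(history, w = NULL) {
  history <- check_history(history)
  if (is.null(w)) {
    params <- fit_w(history)
    west <- params$w
    fitted_w <- TRUE
    identifiable <- params$identifiable
  } else {
    stop_if_not_scalar_number(w, "w", min = 0, max = 1)
    west <- w
    fitted_w <- FALSE
    identifiable <- TRUE
  }
  pred <- if (is.na(west)) NULL else predict_matching(history, west)
  structure(list(
    w = west, fitted_w = fitted_w, identifiable = identifiable,
    history = history, pred = pred,
    msd = if (is.null(pred)) structure(NA_real_, undefined = TRUE)
          else msd(pred$pred, pred$own)
  ), class = "matching_model")
}

#' @export
coef.matching_model <- function(object, ...) c(w = object$w)

#' @export
print.matching_model <- function(x, ...) {
  cat("Matching model of round-by-round contributions\n")
  if (!x$identifiable)
    cat("  w: unidentifiable (lagged contributions never differ)\n")
  else
    cat(sprintf("  w = %.4f (%s), MSD = %.3f over %d predicted rounds\n",
                x$w, if (x$fitted_w) "least squares" else "fixed",
                x$msd, if (is.null(x$pred)) 0L else nrow(x$pred)))
  invisible(x)
}

#' @export
summary.matching_model <- function(object, ...) {
  res <- residuals(object)
  structure(list(w = object$w, fitted_w = object$fitted_w,
                 identifiable = object$identifiable, msd = object$msd,
                 n_pred = length(res),
                 resid_summary = if (length(res)) summary(res) else NULL),
            class = "summary.matching_model")
}

#' @export
print.summary.matching_model <- function(x, ...) {
  cat(sprintf("Matching model: w = %.4f (%s)\n", x$w,
              if (x$fitted_w) "fitted" else "fixed"))
  cat(sprintf("MSD %.3f over %d predicted rounds\n", x$msd, x$n_pred))
  if (!is.null(x$resid_summary)) {
    cat("Residuals:\n"); print(x$resid_summary)
  }
  invisible(x)
}

#' @export
predict.matching_model <- function(object, newdata = NULL, ...) {
  h <- if (is.null(newdata)) object$history else newdata
  if (is.na(object$w)) stop("model has no identifiable weight", call. = FALSE)
  predict_matching(h, object$w)
}

#' @export
fitted.matching_model <- function(object, ...) {
  if (is.null(object$pred)) numeric(0) else object$pred$pred
}

#' @export
residuals.matching_model <- function(object, ...) {
  if (is.null(object$pred)) numeric(0) else object$pred$own - object$pred$pred
}

#' @export
simulate.matching_model <- function(object, nsim = 1, seed = NULL,
                                    n_rounds = 10, noise_sd = 0,
                                    round1 = c(12, 12), ...) {
  if (is.na(object$w)) stop("model has no identifiable weight", call. = FALSE)
  with_seed(seed, {
    lapply(seq_len(nsim), function(s) {
      own <- other <- integer(n_rounds)
      own[1] <- round1[1]; other[1] <- round1[2]
      for (t in seq_len(n_rounds)[-1]) {
        own[t] <- clip(round(object$w * own[t - 1] +
                               (1 - object$w) * other[t - 1] +
                               rnorm(1, 0, noise_sd)), 0, 20)
        other[t] <- clip(round(object$w * other[t - 1] +
                                 (1 - object$w) * own[t - 1] +
                                 rnorm(1, 0, noise_sd)), 0, 20)
      }
      data.frame(game = s, round = seq_len(n_rounds), own = own, other = other)
    })
  })
}

#' Compare contribution models across individuals
#'
#' Scores four models per individual — conditional cooperation with naive
#' and with actual beliefs, the matching model at `w = 0.5`, and the
#' matching model with the individually fitted `w` — on the same predicted
#' rounds, then averages MSDs across individuals (unweighted).
#'
#' @param histories Named list of per-individual history data frames.
#' @return A `model_comparison` list: `per_individual` (data frame of
#'   per-model MSDs and fitted `w`), `grand` (named mean MSDs over
#'   individuals with a defined MSD).
#' @export
compare_models <- function(histories) {
  rows <- lapply(names(histories), function(id) {
    h <- histories[[id]]
    lh <- lagged_history(h)
    if (is.null(lh)) return(NULL)
    fit <- matching_model(h)
    data.frame(
      participant_id = id,
      n_pred = nrow(lh),
      w = fit$w,
      identifiable = fit$identifiable,
      msd_cc_naive = msd(predict_cc_naive(h)$pred, lh$own),
      msd_cc_actual = msd(predict_cc_actual(h)$pred, lh$own),
      msd_matching_w05 = msd(predict_matching(h, 0.5)$pred, lh$own),
      msd_matching_fitted = as.numeric(fit$msd),
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  per <- do.call(rbind, rows)
  models <- c("msd_cc_naive", "msd_cc_actual", "msd_matching_w05",
              "msd_matching_fitted")
  grand <- vapply(models, function(m) mean(per[[m]], na.rm = TRUE), numeric(1))
  structure(list(per_individual = per, grand = grand),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Grand MSD (mean over", nrow(x$per_individual), "individuals):\n")
  print(round(x$grand, 3))
  invisible(x)
}

#' Correlation between fitted weights and relative attention
#'
#' Pearson product-moment correlation between per-individual matching
#' weights and gaze-derived relative attention, with the usual
#' t-transform p value. Unidentifiable individuals (NA in either vector)
#' are dropped.
#'
#' @param w Numeric vector of fitted weights.
#' @param ra Numeric vector of relative-attention ratios, aligned with `w`.
#' @return A list: `r`, `p`, `n`, `conf_int` (95%), `defined`.
#' @export
correlate_w_ra <- function(w, ra) {
  keep <- !is.na(w) & !is.na(ra)
  w <- w[keep]; ra <- ra[keep]
  if (length(w) < 3L || sd(w) == 0 || sd(ra) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(w),
                conf_int = c(NA_real_, NA_real_), defined = FALSE))
  ct <- stats::cor.test(w, ra)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(w),
       conf_int = as.numeric(ct$conf.int), defined = TRUE)
}

#' Slope of relative attention on the contribution difference
#'
#' Ordinary least-squares slope of per-round relative attention on the
#' same round's contribution difference (own minus other). A negative
#' slope means attention shifts toward the other player as one's own
#' contribution exceeds theirs.
#'
#' @param diff Numeric vector of per-round `own - other` differences.
#' @param ra Numeric vector of per-round relative attention, aligned.
#' @return A list: `slope`, `intercept`, `n`, `defined` (FALSE when the
#'   differences have zero variance).
#' @export
ra_vs_contribution_diff <- function(diff, ra) {
  keep <- !is.na(diff) & !is.na(ra)
  diff <- diff[keep]; ra <- ra[keep]
  if (length(diff) < 3L || var(diff) == 0)
    return(list(slope = NA_real_, intercept = NA_real_, n = length(diff),
                defined = FALSE))
  fit <- lm(ra ~ diff)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n = length(diff), defined = TRUE)
}
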