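#' Leave-one-out cross-validated Q2
#'
#' Computes `Q2_LOO = 1 - PRESS / TSS`, where `PRESS` sums squared
#' leave-one-row-out prediction errors and `TSS` sums squared deviations of
#' the used responses from their overall mean. By default the closed-form
#' least-squares identity `e_l / (1 - h_l)` (residual over one minus
#' leverage) supplies the deleted residuals without refitting;
#' `method = "refit"` performs the n explicit refits instead and exists as
#' a cross-check and as the fallback for rows whose removal makes the
#' training design rank-deficient.
#'
#' Rows whose deleted prediction is unavailable (leverage numerically 1, or
#' a refit that cannot predict the row) are excluded from both numerator
#' and denominator and counted in `n_unpredictable`.
#'
#' @param obs An [observation_set()].
#' @param variant Model variant, see [build_design()].
#' @param method `"hat"` (default) or `"refit"`.
#' @return A list of class `lfer_cv` with `q2`, `press`, `n_used`,
#'   `n_unpredictable`.
#' @export
q2_loo <- function(obs, variant = c("single", "crossed", "nested"),
                   method = c("hat", "refit")) {
  variant <- match.arg(variant)
  method <- match.arg(method)
  design <- build_design(obs, variant)
  y <- design$y
  n <- length(y)
  if (method == "hat") {
    fit <- fit_ols(design)
    one_minus_h <- 1 - fit$hat
    ok <- one_minus_h > 1e-8
    del <- rep(NA_real_, n)
    del[ok] <- fit$residuals[ok] / one_minus_h[ok]
  } else {
    rows <- obs$observations
    del <- rep(NA_real_, n)
    for (l in seq_len(n)) {
      train <- observation_set(rows[-l, , drop = FALSE],
                               descriptors = obs$descriptors,
                               levels = obs$levels, permissive = TRUE)
      test <- observation_set(rows[l, , drop = FALSE],
                              descriptors = obs$descriptors,
                              levels = obs$levels, permissive = TRUE)
      f <- tryCatch(fit_lfer(train, variant), error = function(e) NULL)
      if (is.null(f)) next
      pred <- predict_lfer(f, test)
      if (is.finite(pred)) del[l] <- y[l] - pred
    }
    ok <- !is.na(del)
  }
  .finish_cv(y, del, ok, "q2_loo")
}

.finish_cv <- function(y, del, ok, statistic, per_solute_press = NULL) {
  y_used <- y[ok]
  press <- sum(del[ok]^2)
  tss <- sum((y_used - mean(y_used))^2)
  if (tss <= 0) {
    stop("undefined statistic: zero variance among the usable responses",
         call. = FALSE)
  }
  structure(list(
    statistic = statistic,
    q2 = 1 - press / tss,
    press = press,
    n_used = sum(ok),
    n_unpredictable = sum(!ok),
    per_solute_press = per_solute_press
  ), class = "lfer_cv")
}

#' @export
print.lfer_cv <- function(x, ...) {
  cat(sprintf("<lfer_cv> %s = %.4f (n_used=%d, unpredictable=%d)\n",
              x$statistic, x$q2, x$n_used, x$n_unpredictable))
  invisible(x)
}

#' Leave-one-solute-out cross-validated Q2
#'
#' For each distinct solute `s`, refits the model on every observation not
#' belonging to `s` and predicts all of `s`'s rows from that fit;
#' `Q2_LOSO = 1 - sum of squared errors / TSS` over the usable rows. With
#' replicates in the data, leave-one-row-out folds retain a solute's
#' sibling replicates and overstate predictive power for unseen solutes;
#' leaving the whole solute out removes that optimism, which is why this is
#' the headline predictive statistic for the expanded models.
#'
#' Group deletion has no leverage shortcut, so each fold is a genuine
#' refit. Rows a training fold cannot predict (their cell block absent or
#' rank-deficient without that solute) are excluded from numerator and
#' denominator and counted in `n_unpredictable`.
#'
#' @inheritParams q2_loo
#' @return A list of class `lfer_cv` with `q2`, `press`, `n_used`,
#'   `n_unpredictable` and `per_solute_press`.
#' @export
q2_loso <- function(obs, variant = c("single", "crossed", "nested")) {
  variant <- match.arg(variant)
  rows <- obs$observations
  y <- rows$log_k
  solutes <- sort(unique(rows$solute_id))
  del <- rep(NA_real_, length(y))
  per_press <- stats::setNames(rep(NA_real_, length(solutes)),
                               as.character(solutes))
  for (s in solutes) {
    hold <- rows$solute_id == s
    train <- observation_set(rows[!hold, , drop = FALSE],
                             descriptors = obs$descriptors,
                             levels = obs$levels, permissive = TRUE)
    test <- observation_set(rows[hold, , drop = FALSE],
                            descriptors = obs$descriptors,
                            levels = obs$levels, permissive = TRUE)
    f <- tryCatch(fit_lfer(train, variant), error = function(e) NULL)
    if (is.null(f)) next
    pred <- predict_lfer(f, test)
    err <- y[hold] - pred
    del[hold] <- err
    per_press[as.character(s)] <- sum(err[is.finite(err)]^2)
  }
  ok <- !is.na(del)
  .finish_cv(y, del, ok, "q2_loso", per_solute_press = per_press)
}

#' Fit-statistics table for the three LFER variants
#'
#' Fits the single, crossed and nested models to the same observation set
#' and reports `r2`, `adj_r2`, `q2_loo` and `q2_loso` for each — the
#' standard model-comparison summary for this analysis.
#'
#' @param obs An [observation_set()].
#' @param variants Which variants to include (default all three).
#' @return Data frame with one row per variant and columns `model`, `r2`,
#'   `adj_r2`, `q2_loo`, `q2_loso`, `n_unpredictable_loo`,
#'   `n_unpredictable_loso`.
#' @export
fit_statistics_table <- function(obs,
                                 variants = c("single", "crossed",
                                              "nested")) {
  out <- lapply(variants, function(v) {
    fit <- fit_lfer(obs, v)
    loo <- q2_loo(obs, v)
    loso <- q2_loso(obs, v)
    data.frame(model = v, r2 = fit$r2, adj_r2 = fit$adj_r2,
               q2_loo = loo$q2, q2_loso = loso$q2,
               n_unpredictable_loo = loo$n_unpredictable,
               n_unpredictable_loso = loso$n_unpredictable,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
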