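#' Ordinary least squares for an LFER design
#'
#' Fits the supplied design by least squares. Because the expanded variants
#' use cell-means coding, the normal equations decompose over cells: each
#' coefficient block is estimated from its own cell's rows via a
#' rank-revealing QR decomposition (relative pivot tolerance 1e-10), which
#' makes leave-one-solute-out refits of the 540-column crossed design cheap.
#' Point estimates are identical to a full-matrix fit.
#'
#' The residual variance is pooled across all cells of the single model
#' (one sigma^2, `df_resid = n - rank`), standard errors are derived from
#' it, and confidence intervals use Student-t quantiles at `df_resid`
#' degrees of freedom. Columns that are collinear within their block (for
#' example `A` in a cell where every observed solute has `A = 0`) are
#' dropped and reported in `dropped_columns`; their coefficients are `NA`.
#'
#' @param design An [build_design()] result.
#' @param y Response vector (`log10 K`); defaults to the responses carried
#'   by the design.
#' @param ci_level Confidence level for coefficient intervals, default 0.95.
#' @return An object of class `lfer_fit` with named coefficient vector
#'   (`NA` for dropped columns), `se`, `ci_low`, `ci_high`, `fitted`,
#'   `residuals`, `hat` (leverages), `sigma2`, `df_resid`, `r2`, `adj_r2`,
#'   `rank`, `dropped_columns` and the design metadata.
#' @export
fit_ols <- function(design, y = design$y, ci_level = 0.95) {
  stopifnot(inherits(design, "lfer_design"))
  X <- design$X
  n <- nrow(X)
  if (length(y) != n) stop("length(y) must match nrow(design$X)",
                           call. = FALSE)
  if (anyNA(y)) stop("response contains NA", call. = FALSE)

  p <- ncol(X)
  coefs <- stats::setNames(rep(NA_real_, p), colnames(X))
  unscaled <- stats::setNames(rep(NA_real_, p), colnames(X))
  fitted <- numeric(n)
  hat <- numeric(n)
  rank_total <- 0L
  dropped <- character(0)
  collinear_map <- list()

  cell_of_col <- design$col_meta$cell
  blocks <- if (all(is.na(cell_of_col))) {
    list(list(rid = seq_len(n), cid = seq_len(p)))
  } else {
    lapply(unique(cell_of_col), function(cl) {
      list(rid = which(design$row_meta$cell == cl),
           cid = which(cell_of_col == cl))
    })
  }

  for (blk in blocks) {
    rid <- blk$rid; cid <- blk$cid
    Xb <- X[rid, cid, drop = FALSE]
    qb <- qr(Xb, tol = 1e-10)
    r <- qb$rank
    rank_total <- rank_total + r
    beta <- qr.coef(qb, y[rid])
    keep <- !is.na(beta)
    coefs[cid] <- beta
    dropped <- c(dropped, colnames(Xb)[!keep])
    fitted[rid] <- qr.fitted(qb, y[rid])
    if (r > 0L) {
      Q <- qr.Q(qb)[, seq_len(r), drop = FALSE]
      hat[rid] <- rowSums(Q * Q)
      Rfull <- qr.R(qb)
      R <- Rfull[seq_len(r), seq_len(r), drop = FALSE]
      Rinv <- backsolve(R, diag(r))
      # diag of (X'X)^-1 for retained columns, in pivoted order
      unscaled[cid[qb$pivot[seq_len(r)]]] <- rowSums(Rinv * Rinv)
      if (r < ncol(Xb)) {
        # each dropped column is an exact combination of the kept ones;
        # keep that representation so estimable predictions survive
        kept_names <- colnames(Xb)[qb$pivot[seq_len(r)]]
        A <- backsolve(R, Rfull[seq_len(r), -seq_len(r), drop = FALSE])
        drop_names <- colnames(Xb)[qb$pivot[-seq_len(r)]]
        for (dj in seq_along(drop_names)) {
          collinear_map[[drop_names[dj]]] <-
            stats::setNames(A[, dj], kept_names)
        }
      }
    }
  }

  df_resid <- n - rank_total
  if (df_resid < 1L) {
    sat <- vapply(blocks, function(blk) {
      r <- blk$rid
      length(r) <= qr(X[r, blk$cid, drop = FALSE], tol = 1e-10)$rank
    }, NA)
    bad <- unique(design$row_meta$cell[unlist(
      lapply(blocks[sat], `[[`, "rid"))])
    stop("model is saturated (no residual degrees of freedom); ",
         "deficient cells: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  res <- y - fitted
  sse <- sum(res^2)
  sigma2 <- sse / df_resid
  se <- sqrt(sigma2 * unscaled)
  tcrit <- stats::qt(1 - (1 - ci_level) / 2, df_resid)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sse / tss else NA_real_
  adj_r2 <- if (tss > 0) 1 - (1 - r2) * (n - 1) / df_resid else NA_real_

  structure(list(
    variant = design$variant,
    coefficients = coefs,
    se = se,
    ci_low = coefs - tcrit * se,
    ci_high = coefs + tcrit * se,
    ci_level = ci_level,
    fitted = fitted,
    residuals = res,
    hat = hat,
    sigma2 = sigma2,
    df_resid = df_resid,
    rank = rank_total,
    n = n,
    r2 = r2,
    adj_r2 = adj_r2,
    dropped_columns = dropped,
    collinear_map = collinear_map,
    col_meta = design$col_meta,
    row_meta = design$row_meta,
    include_t = design$include_t
  ), class = "lfer_fit")
}

#' Fit an LFER variant to an observation set
#'
#' Convenience wrapper: builds the design with [build_design()] and fits it
#' with [fit_ols()].
#'
#' @inheritParams build_design
#' @inheritParams fit_ols
#' @return An `lfer_fit`.
#' @export
fit_lfer <- function(obs, variant = c("single", "crossed", "nested"),
                     ci_level = 0.95, include_t = TRUE) {
  fit_ols(build_design(obs, variant, include_t = include_t),
          ci_level = ci_level)
}

#' @export
print.lfer_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "<lfer_fit> variant=%s: n=%d, rank=%d, df_resid=%d\n",
    "  r2=%.4f adj_r2=%.4f sigma=%.4f, %d dropped column(s)\n"),
    x$variant, x$n, x$rank, x$df_resid, x$r2, x$adj_r2,
    sqrt(x$sigma2), length(x$dropped_columns)))
  invisible(x)
}

#' Coefficient table of a fit
#'
#' @param fit An `lfer_fit`.
#' @return Data frame with columns `cell`, `descriptor`, `estimate`, `se`,
#'   `ci_low`, `ci_high` (one row per design column; dropped columns carry
#'   `NA`).
#' @export
coef_table <- function(fit) {
  stopifnot(inherits(fit, "lfer_fit"))
  data.frame(cell = fit$col_meta$cell,
             descriptor = fit$col_meta$descriptor,
             estimate = unname(fit$coefficients),
             se = unname(fit$se),
             ci_low = unname(fit$ci_low),
             ci_high = unname(fit$ci_high),
             stringsAsFactors = FALSE)
}

#' Fit the single LFER model separately within each treatment cell
#'
#' Applies the six-parameter single LFER model independently to the rows of
#' each populated (MWF, MWF concentration, solute concentration) cell.
#' Unlike the pooled crossed fit, each cell here uses its own residual
#' variance for standard errors. Cells with fewer than `min_rows`
#' observations (default 7: six parameters plus one residual degree of
#' freedom) are skipped and reported.
#'
#' @param obs An [observation_set()].
#' @param ci_level Confidence level, default 0.95.
#' @param min_rows Minimum rows for a cell to be fitted, default 7.
#' @return A list of class `per_cell_fits` with `fits` (named list of
#'   `lfer_fit` keyed by cell label) and `skipped` (data frame of cell,
#'   n and reason).
#' @export
fit_per_cell <- function(obs, ci_level = 0.95, min_rows = 7L) {
  stopifnot(inherits(obs, "observation_set"))
  rows <- obs$observations
  cells <- .order_cells(
    unique(cell_id(rows$mwf, rows$mwf_conc, rows$solute_conc)),
    obs$levels, "crossed")
  fits <- list()
  skipped <- data.frame(cell = character(0), n = integer(0),
                        reason = character(0), stringsAsFactors = FALSE)
  lab <- cell_id(rows$mwf, rows$mwf_conc, rows$solute_conc)
  for (cl in cells) {
    sub <- rows[lab == cl, , drop = FALSE]
    if (nrow(sub) < min_rows) {
      skipped <- rbind(skipped, data.frame(
        cell = cl, n = nrow(sub),
        reason = "insufficient df", stringsAsFactors = FALSE))
      next
    }
    sub_obs <- observation_set(sub, descriptors = obs$descriptors,
                               levels = obs$levels, permissive = TRUE)
    fits[[cl]] <- fit_lfer(sub_obs, "single", ci_level = ci_level)
  }
  structure(list(fits = fits, skipped = skipped), class = "per_cell_fits")
}

#' @export
print.per_cell_fits <- function(x, ...) {
  cat(sprintf("<per_cell_fits> %d cells fitted, %d skipped\n",
              length(x$fits), nrow(x$skipped)))
  invisible(x)
}

#' Per-cell coefficient table
#'
#' Flattens [fit_per_cell()] output into one row per (cell, descriptor),
#' the layout of a per-treatment coefficient report.
#'
#' @param per_cell A `per_cell_fits` object.
#' @return Data frame with columns `cell`, `descriptor`, `estimate`, `se`,
#'   `ci_low`, `ci_high`, `n`.
#' @export
per_cell_coef_table <- function(per_cell) {
  stopifnot(inherits(per_cell, "per_cell_fits"))
  out <- lapply(names(per_cell$fits), function(cl) {
    f <- per_cell$fits[[cl]]
    cbind(cell = cl, coef_table(f)[, -1L], n = f$n)
  })
  do.call(rbind, out)
}

#' Predict log K for new observations
#'
#' Applies a fitted LFER model to new rows. A prediction is reported as
#' `NA` (and is counted by the cross-validation routines as unpredictable)
#' when the row activates a coefficient block that was absent from the
#' training design, or when it loads on a column that was dropped for
#' collinearity during training *and* its covariate vector is not an
#' estimable function of the training design (rows that replicate the
#' collinearity pattern seen in training are still predictable, since
#' their mean is invariant to the choice of generalised inverse).
#'
#' @param fit An `lfer_fit`.
#' @param new_obs An [observation_set()] of rows to predict.
#' @return Numeric vector of predicted `log10 K`, `NA` where unavailable.
#' @export
predict_lfer <- function(fit, new_obs) {
  stopifnot(inherits(fit, "lfer_fit"), inherits(new_obs, "observation_set"))
  nd <- build_design(new_obs, fit$variant, include_t = fit$include_t)
  beta <- fit$coefficients[match(colnames(nd$X), names(fit$coefficients))]
  beta_zeroed <- ifelse(is.na(beta), 0, beta)
  pred <- drop(nd$X %*% beta_zeroed)
  miss <- colnames(nd$X)[is.na(beta)]
  for (col in miss) {
    xj <- nd$X[, col]
    rows <- which(xj != 0)
    if (length(rows) == 0L) next
    aj <- fit$collinear_map[[col]]
    if (is.null(aj)) { # column (or its whole block) absent from training
      pred[rows] <- NA_real_
      next
    }
    implied <- drop(nd$X[rows, names(aj), drop = FALSE] %*% aj)
    bad <- abs(xj[rows] - implied) > 1e-8 * pmax(1, abs(xj[rows]))
    pred[rows[bad]] <- NA_real_
  }
  pred
}
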