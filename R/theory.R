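#' Global test of the partition theory
#'
#' Under the partition theory, `K_MCF/mix` does not depend on the starting
#' solute concentration, so in the nested LFER model every per-cell slope
#' on `t = log10(solute_conc)` is zero:
#'
#'   H0: beta_t(i,j) = 0 for every MWF i and MWF concentration j.
#'
#' The test is the extra sum-of-squares F test comparing the full nested
#' model against the reduced nested model with all `t` columns removed,
#' with numerator degrees of freedom equal to the number of `t` slopes the
#' data can estimate.
#'
#' @param obs An [observation_set()].
#' @return A list of class `partition_theory_test` with `f`, `df`
#'   (numerator, denominator), `p_value`, `n_obs`, `sse_full`,
#'   `sse_reduced`.
#' @export
test_partition_global <- function(obs) {
  full <- fit_lfer(obs, "nested")
  reduced <- fit_lfer(obs, "nested", include_t = FALSE)
  q <- full$rank - reduced$rank
  if (q < 1L) {
    stop("degenerate test: no estimable solute-concentration slope ",
         "(need >= 2 distinct solute concentrations within some cell)",
         call. = FALSE)
  }
  sse_full <- sum(full$residuals^2)
  sse_red <- sum(reduced$residuals^2)
  f <- ((sse_red - sse_full) / q) / (sse_full / full$df_resid)
  structure(list(
    f = f,
    df = c(q, full$df_resid),
    p_value = stats::pf(f, q, full$df_resid, lower.tail = FALSE),
    n_obs = full$n,
    sse_full = sse_full,
    sse_reduced = sse_red
  ), class = "partition_theory_test")
}

#' @export
print.partition_theory_test <- function(x, ...) {
  cat(sprintf(
    "<partition_theory_test> F(%d, %d) = %.3f, p = %.3g (n = %d)\n",
    x$df[1], x$df[2], x$f, x$p_value, x$n_obs))
  invisible(x)
}

#' Per-cell tests of the solute-concentration slope
#'
#' From the pooled nested fit (a single model, one pooled residual
#' variance), tests `beta_t(i,j) = 0` in each (MWF, MWF concentration)
#' cell with a t statistic at `df_resid` degrees of freedom. Significance
#' is called at `alpha / divisor`; by default the Bonferroni divisor stays
#' fixed at the 15 cells of the full design even when fewer are estimable
#' (`divisor = "tested"` divides by the number actually tested instead).
#'
#' @param obs An [observation_set()].
#' @param alpha Family-wise level, default 0.05.
#' @param divisor Either `"design"` (default: the number of
#'   (MWF, MWF conc) cells in the declared level sets, 15 for the study
#'   design) or `"tested"`.
#' @return A list of class `partition_cell_tests` with `per_cell` (data
#'   frame: cell, n_obs, estimate, se, t, p_value, significant),
#'   `unestimable` (cells whose `t` column was dropped or absent),
#'   `alpha`, `n_cells_tested`, `threshold`.
#' @export
test_partition_cells <- function(obs, alpha = 0.05,
                                 divisor = c("design", "tested")) {
  divisor <- match.arg(divisor)
  fit <- fit_lfer(obs, "nested")
  cm <- fit$col_meta
  is_t <- cm$descriptor == "t"
  est <- fit$coefficients[is_t]
  se <- fit$se[is_t]
  cells <- cm$cell[is_t]
  n_cell <- table(fit$row_meta$cell)
  ok <- !is.na(est)
  tstat <- est[ok] / se[ok]
  p <- 2 * stats::pt(-abs(tstat), fit$df_resid)
  n_design <- length(obs$levels$mwf) * length(obs$levels$mwf_conc)
  div <- if (divisor == "design") n_design else sum(ok)
  threshold <- alpha / div
  per_cell <- data.frame(
    cell = cells[ok],
    n_obs = as.integer(n_cell[cells[ok]]),
    estimate = unname(est[ok]),
    se = unname(se[ok]),
    t = unname(tstat),
    p_value = unname(p),
    significant = unname(p < threshold),
    stringsAsFactors = FALSE)
  structure(list(
    per_cell = per_cell,
    unestimable = cells[!ok],
    alpha = alpha,
    n_cells_tested = sum(ok),
    bonferroni_divisor = div,
    threshold = threshold,
    df_resid = fit$df_resid
  ), class = "partition_cell_tests")
}

#' @export
print.partition_cell_tests <- function(x, ...) {
  cat(sprintf(paste0(
    "<partition_cell_tests> %d cells tested at %.3g/%d = %.2e: ",
    "%d significant, %d not; %d unestimable\n"),
    x$n_cells_tested, x$alpha, x$bonferroni_divisor, x$threshold,
    sum(x$per_cell$significant), sum(!x$per_cell$significant),
    length(x$unestimable)))
  invisible(x)
}

#' Default solute-concentration subsets for the theory battery
#'
#' The global and per-cell tests are repeated on nested subsets of the six
#' study solute concentrations, asking whether the partition theory holds
#' at least over a restricted concentration range.
#'
#' @return Named list of concentration vectors (ppm).
#' @export
default_concentration_subsets <- function() {
  list(
    "All" = c(0.01, 0.05, 0.1, 0.5, 1, 5),
    "0.01-1" = c(0.01, 0.05, 0.1, 0.5, 1),
    "0.01-0.5" = c(0.01, 0.05, 0.1, 0.5),
    "0.01-0.1" = c(0.01, 0.05, 0.1),
    "0.05-0.5" = c(0.05, 0.1, 0.5),
    "0.01-0.05" = c(0.01, 0.05),
    "0.05-0.1" = c(0.05, 0.1)
  )
}

#' Restrict an observation set to selected solute concentrations
#'
#' @param obs An [observation_set()].
#' @param concs Solute concentrations (ppm) to keep.
#' @return A filtered `observation_set`.
#' @export
filter_concentrations <- function(obs, concs) {
  stopifnot(inherits(obs, "observation_set"))
  keep <- .num_in(obs$observations$solute_conc, concs)
  observation_set(obs$observations[keep, , drop = FALSE],
                  descriptors = obs$descriptors, levels = obs$levels,
                  permissive = TRUE)
}

#' Partition-theory tests over solute-concentration subsets
#'
#' For each subset the observation set is filtered to the listed
#' concentrations, `t` is rebuilt, and both [test_partition_global()] and
#' [test_partition_cells()] are rerun, yielding one report row per subset:
#' the global p-value, the cells whose slope is not significantly
#' different from zero at `alpha/15` (supporting the theory) and the cells
#' that violate it, each with its sample size.
#'
#' @param obs An [observation_set()].
#' @param subsets Named list of concentration vectors, default
#'   [default_concentration_subsets()].
#' @param alpha Family-wise level, default 0.05.
#' @param divisor Bonferroni divisor rule, see [test_partition_cells()].
#' @return A list of class `partition_subset_analysis`: `table` (one row
#'   per subset: subset, n_obs, global_f, global_p, insignificant_cells,
#'   significant_cells) and `reports` (the per-subset test objects).
#' @export
subset_analysis <- function(obs, subsets = default_concentration_subsets(),
                            alpha = 0.05, divisor = c("design", "tested")) {
  divisor <- match.arg(divisor)
  if (is.null(names(subsets))) {
    names(subsets) <- vapply(subsets, function(s)
      paste(.fmt_num(s), collapse = ","), "")
  }
  reports <- list()
  rows <- list()
  for (nm in names(subsets)) {
    concs <- subsets[[nm]]
    present <- unique(obs$observations$solute_conc[
      .num_in(obs$observations$solute_conc, concs)])
    if (length(present) < 2L) {
      stop(sprintf(paste0(
        "subset '%s' leaves %d distinct solute concentration(s); ",
        "at least 2 are needed to estimate a concentration slope"),
        nm, length(present)), call. = FALSE)
    }
    sub <- filter_concentrations(obs, concs)
    glob <- test_partition_global(sub)
    cells <- test_partition_cells(sub, alpha = alpha, divisor = divisor)
    pc <- cells$per_cell
    fmt_cells <- function(idx) {
      if (!any(idx)) return("")
      paste(sprintf("%s(%d)", pc$cell[idx], pc$n_obs[idx]), collapse = ", ")
    }
    reports[[nm]] <- list(global = glob, cells = cells)
    rows[[nm]] <- data.frame(
      subset = nm,
      n_obs = glob$n_obs,
      global_f = glob$f,
      global_p = glob$p_value,
      insignificant_cells = fmt_cells(!pc$significant),
      significant_cells = fmt_cells(pc$significant),
      stringsAsFactors = FALSE)
  }
  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 reports = reports, alpha = alpha),
            class = "partition_subset_analysis")
}

#' @export
print.partition_subset_analysis <- function(x, ...) {
  cat("<partition_subset_analysis>\n")
  tab <- x$table
  for (r in seq_len(nrow(tab))) {
    cat(sprintf("  %-10s n=%5d  p=%.3g  supporting: %s\n",
                tab$subset[r], tab$n_obs[r], tab$global_p[r],
                ifelse(nzchar(tab$insignificant_cells[r]),
                       tab$insignificant_cells[r], "none")))
  }
  invisible(x)
}
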