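#' @title Observation sets
#' @description
#' The unit of record is one replicate measurement of `log10 K_MCF/mix` for
#' one solute in one treatment cell: a metalworking fluid (`mwf`), an MWF
#' concentration in percent (`mwf_conc`) and a solute concentration in ppm
#' (`solute_conc`). An `observation_set` bundles the long table of such rows
#' with the descriptor table that resolves every `solute_id`.
#' @name observation_set
NULL

.obs_cols <- c("solute_id", "mwf", "mwf_conc", "solute_conc", "t",
               "replicate", "log_k")

.fmt_num <- function(x) format(x, trim = TRUE, scientific = FALSE,
                               drop0trailing = TRUE)

#' Label treatment cells
#'
#' `cell_id()` labels a full (MWF, MWF concentration, solute concentration)
#' treatment combination; `mwf_cell_id()` labels the coarser
#' (MWF, MWF concentration) combination used by the nested model.
#'
#' @param mwf,mwf_conc,solute_conc Vectors of factor levels.
#' @return Character labels such as `"MO/0.05/0.01"` or `"MO/0.05"`.
#' @export
cell_id <- function(mwf, mwf_conc, solute_conc) {
  paste(mwf, .fmt_num(mwf_conc), .fmt_num(solute_conc), sep = "/")
}

#' @rdname cell_id
#' @export
mwf_cell_id <- function(mwf, mwf_conc) {
  paste(mwf, .fmt_num(mwf_conc), sep = "/")
}

#' Construct an observation set
#'
#' @param observations Data frame with columns `solute_id`, `mwf`,
#'   `mwf_conc`, `solute_conc`, `replicate` and `log_k`. The predictor
#'   `t = log10(solute_conc)` is always recomputed here, never taken from the
#'   input, so the invariant `t == log10(solute_conc)` holds by construction.
#' @param descriptors Descriptor table covering every `solute_id` present
#'   (default: the packaged 37-solute table).
#' @param levels Level sets to validate against (default [study_levels()]).
#' @param permissive If `TRUE`, factor levels outside `levels` are accepted;
#'   the design then generalises beyond the 90-cell study geometry.
#' @return An object of class `observation_set`: a list with elements
#'   `observations` (the long table) and `descriptors`.
#' @export
observation_set <- function(observations,
                            descriptors = load_solute_table(),
                            levels = study_levels(),
                            permissive = FALSE) {
  need <- setdiff(.obs_cols, c("t", names(observations)))
  if (length(need) > 0L) {
    stop("observations are missing column(s): ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  obs <- as.data.frame(observations, stringsAsFactors = FALSE)
  obs$solute_id <- as.integer(obs$solute_id)
  obs$mwf <- as.character(obs$mwf)
  obs$mwf_conc <- as.numeric(obs$mwf_conc)
  obs$solute_conc <- as.numeric(obs$solute_conc)
  obs$replicate <- as.integer(obs$replicate)
  obs$log_k <- as.numeric(obs$log_k)
  if (any(obs$solute_conc <= 0, na.rm = TRUE)) {
    stop("solute_conc must be positive (ppm)", call. = FALSE)
  }
  if (!permissive) {
    bad_lvl <- !(obs$mwf %in% levels$mwf) |
      !.num_in(obs$mwf_conc, levels$mwf_conc) |
      !.num_in(obs$solute_conc, levels$solute_conc)
    if (any(bad_lvl)) {
      stop(sprintf(paste0(
        "row %d has a factor level outside the study design ",
        "(MWF in {%s}; MWF conc in {%s} percent; solute conc in {%s} ppm); ",
        "pass permissive = TRUE to accept it"),
        which(bad_lvl)[1L],
        paste(levels$mwf, collapse = ", "),
        paste(.fmt_num(levels$mwf_conc), collapse = ", "),
        paste(.fmt_num(levels$solute_conc), collapse = ", ")),
        call. = FALSE)
    }
  }
  unknown <- setdiff(obs$solute_id, descriptors$solute_id)
  if (length(unknown) > 0L) {
    stop("solute_id without descriptor record: ",
         paste(sort(unknown), collapse = ", "), call. = FALSE)
  }
  obs$t <- log10(obs$solute_conc)
  obs <- obs[, .obs_cols]
  structure(list(observations = obs, descriptors = descriptors,
                 levels = levels),
            class = "observation_set")
}

.num_in <- function(x, set, tol = 1e-9) {
  ok <- rep(FALSE, length(x))
  for (s in set) ok <- ok | abs(x - s) < tol
  ok
}

#' @export
print.observation_set <- function(x, ...) {
  obs <- x$observations
  cat(sprintf("<observation_set> %d rows, %d solutes, %d populated cells\n",
              nrow(obs), length(unique(obs$solute_id)),
              length(unique(cell_id(obs$mwf, obs$mwf_conc,
                                    obs$solute_conc)))))
  invisible(x)
}

#' Read observations from a long-format CSV
#'
#' The file carries one row per replicate. It must contain either a `log_k`
#' column (base-10 log of the partition coefficient) or the four raw
#' extraction columns `n0`, `C0`, `Vd`, `Vm`, from which `log_k` is derived
#' via [partition_coefficient()]. Rows whose derived coefficient is zero
#' (no extraction, `n0 = 0`) have no finite `log_k` and are dropped with a
#' warning.
#'
#' @param path CSV file path.
#' @param descriptors,levels,permissive Passed to [observation_set()].
#' @return An `observation_set`.
#' @export
load_observations <- function(path, descriptors = load_solute_table(),
                              levels = study_levels(), permissive = FALSE) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  raw_cols <- c("n0", "C0", "Vd", "Vm")
  if (!("log_k" %in% names(tab))) {
    if (!all(raw_cols %in% names(tab))) {
      stop("observation file needs either a log_k column or all of ",
           paste(raw_cols, collapse = ", "), call. = FALSE)
    }
    pc <- partition_coefficient(tab$n0, tab$C0, tab$Vd, tab$Vm)
    tab$log_k <- pc$log_k
  }
  zero_k <- is.na(tab$log_k)
  if (any(zero_k)) {
    warning(sum(zero_k), " row(s) without a finite log_k (zero extraction)",
            " were dropped")
    tab <- tab[!zero_k, , drop = FALSE]
  }
  orphan <- !(as.integer(tab$solute_id) %in% descriptors$solute_id)
  if (any(orphan)) {
    warning(sum(orphan), " row(s) with solute_id absent from the ",
            "descriptor table were rejected")
    tab <- tab[!orphan, , drop = FALSE]
  }
  observation_set(tab, descriptors = descriptors, levels = levels,
                  permissive = permissive)
}

#' Write an observation set to CSV
#'
#' Numeric fields are written with enough digits (15 significant) that a
#' read-back via [load_observations()] round-trips within 12 significant
#' digits.
#'
#' @param obs An `observation_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  stopifnot(inherits(obs, "observation_set"))
  out <- obs$observations
  out$log_k <- formatC(out$log_k, digits = 15, format = "g")
  out$t <- formatC(out$t, digits = 15, format = "g")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate an observation set against the study geometry
#'
#' Reports (never raises): the row count, how many of the treatment cells in
#' the declared level sets are populated or empty, and offending rows
#' (duplicate replicate keys, missing or non-finite responses).
#'
#' @param obs An `observation_set`.
#' @return A list of class `validation_report` with fields `n_rows`,
#'   `n_cells_populated`, `n_cells_empty`, `cell_counts` and
#'   `offending_rows` (data frame of row index and reason).
#' @export
validate_observations <- function(obs) {
  stopifnot(inherits(obs, "observation_set"))
  rows <- obs$observations
  lv <- obs$levels
  all_cells <- as.vector(outer(
    as.vector(outer(lv$mwf, .fmt_num(lv$mwf_conc), paste, sep = "/")),
    .fmt_num(lv$solute_conc), paste, sep = "/"))
  have <- cell_id(rows$mwf, rows$mwf_conc, rows$solute_conc)
  counts <- table(factor(have, levels = all_cells))
  offending <- data.frame(row = integer(0), reason = character(0),
                          stringsAsFactors = FALSE)
  key <- paste(rows$solute_id, have, rows$replicate, sep = "|")
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    offending <- rbind(offending, data.frame(
      row = dup, reason = "duplicate (solute, cell, replicate) key"))
  }
  bad_y <- which(!is.finite(rows$log_k))
  if (length(bad_y) > 0L) {
    offending <- rbind(offending, data.frame(
      row = bad_y, reason = "non-finite log_k"))
  }
  structure(list(
    n_rows = nrow(rows),
    n_cells_populated = sum(counts > 0L),
    n_cells_empty = sum(counts == 0L),
    cell_counts = counts,
    offending_rows = offending
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> %d rows; %d/%d cells populated; %d offending rows\n",
    x$n_rows, x$n_cells_populated,
    x$n_cells_populated + x$n_cells_empty, nrow(x$offending_rows)))
  invisible(x)
}
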