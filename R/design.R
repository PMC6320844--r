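#' Build the design matrix for an LFER model variant
#'
#' Three variants of the linear free-energy relationship model are
#' supported, all regressing `log10 K_MCF/mix` on the Abraham descriptors:
#'
#' * `single`: one set of six coefficients (intercept, E, S, A, B, V) shared
#'   by every observation.
#' * `crossed`: cell-means coding over the full treatment combinations
#'   (MWF x MWF concentration x solute concentration). Each populated cell
#'   gets its own block of six coefficients and an observation activates
#'   exactly one block; with all 90 cells populated the design has
#'   90 x 6 = 540 columns.
#' * `nested`: cell-means coding over (MWF x MWF concentration) only, with
#'   solute concentration entering numerically through
#'   `t = log10(solute_conc)`. Each populated (MWF, MWF conc) cell gets a
#'   block of seven coefficients (intercept, E, S, A, B, V, t); with all 15
#'   cells populated the design has 15 x 7 = 105 columns.
#'
#' Cell-means coding is used exactly (a full independent block per cell, no
#' reference level, no shared intercept), so the cross-product matrix is
#' block-diagonal over cells and the pooled fit's point estimates coincide
#' with independent per-cell fits.
#'
#' @param obs An [observation_set()].
#' @param variant One of `"single"`, `"crossed"`, `"nested"`.
#' @param include_t For the nested variant only: include the per-cell
#'   `t = log10(solute_conc)` column (default `TRUE`). Setting it `FALSE`
#'   yields the reduced design used by the partition-theory F test.
#' @return An object of class `lfer_design`: a list with the numeric matrix
#'   `X`, `col_meta` (data frame mapping each column to a descriptor and a
#'   cell label), `row_meta` (solute and cell labels per row), `y` (the
#'   responses, for convenience) and `variant`.
#' @export
build_design <- function(obs, variant = c("single", "crossed", "nested"),
                         include_t = TRUE) {
  variant <- match.arg(variant)
  stopifnot(inherits(obs, "observation_set"))
  rows <- obs$observations
  if (nrow(rows) == 0L) stop("observation set is empty", call. = FALSE)
  desc <- obs$descriptors
  D <- as.matrix(desc[match(rows$solute_id, desc$solute_id),
                      .descriptor_cols, drop = FALSE])
  base <- cbind(`(Intercept)` = 1, D)

  if (variant == "single") {
    X <- base
    col_meta <- data.frame(column = colnames(X),
                           descriptor = colnames(X),
                           cell = NA_character_,
                           stringsAsFactors = FALSE)
    row_cell <- rep(NA_character_, nrow(rows))
  } else {
    if (variant == "crossed") {
      row_cell <- cell_id(rows$mwf, rows$mwf_conc, rows$solute_conc)
      block <- base
    } else {
      row_cell <- mwf_cell_id(rows$mwf, rows$mwf_conc)
      block <- if (include_t) cbind(base, t = rows$t) else base
    }
    cells <- .order_cells(unique(row_cell), obs$levels, variant)
    bw <- ncol(block)
    X <- matrix(0, nrow(rows), bw * length(cells))
    descs <- colnames(block)
    colnames(X) <- paste(rep(cells, each = bw), rep(descs, length(cells)),
                         sep = ":")
    cf <- match(row_cell, cells)
    for (b in seq_along(cells)) {
      rid <- which(cf == b)
      X[rid, (b - 1L) * bw + seq_len(bw)] <- block[rid, , drop = FALSE]
    }
    col_meta <- data.frame(column = colnames(X),
                           descriptor = rep(descs, length(cells)),
                           cell = rep(cells, each = bw),
                           stringsAsFactors = FALSE)
  }
  structure(list(
    X = X,
    col_meta = col_meta,
    row_meta = data.frame(rows[, c("solute_id", "mwf", "mwf_conc",
                                   "solute_conc", "replicate")],
                          cell = row_cell, stringsAsFactors = FALSE),
    y = rows$log_k,
    variant = variant,
    include_t = include_t
  ), class = "lfer_design")
}

# order populated cells in design order: MWF, then MWF conc, then solute conc
.order_cells <- function(cells, levels, variant) {
  parts <- strsplit(cells, "/", fixed = TRUE)
  i <- match(vapply(parts, `[[`, "", 1L), levels$mwf)
  j <- match(as.numeric(vapply(parts, `[[`, "", 2L)), levels$mwf_conc)
  if (variant == "crossed") {
    k <- match(as.numeric(vapply(parts, `[[`, "", 3L)), levels$solute_conc)
  } else {
    k <- integer(length(cells))
  }
  i[is.na(i)] <- length(levels$mwf) + 1L
  j[is.na(j)] <- length(levels$mwf_conc) + 1L
  k[is.na(k)] <- length(levels$solute_conc) + 1L
  cells[order(i, j, k, cells)]
}

#' @export
print.lfer_design <- function(x, ...) {
  cat(sprintf("<lfer_design> variant=%s, %d rows x %d columns (%d blocks)\n",
              x$variant, nrow(x$X), ncol(x$X),
              length(unique(x$col_meta$cell))))
  invisible(x)
}
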