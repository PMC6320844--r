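#' Study factor levels
#'
#' The treatment design crosses five metalworking fluids (MWFs) with three
#' MWF concentrations (percent) and six solute concentrations (ppm, i.e.
#' ug/mL), giving 5 x 3 x 6 = 90 treatment combinations ("cells").
#'
#' @return A named list with components `mwf`, `mwf_conc` and `solute_conc`
#'   holding the default level sets.
#' @export
study_levels <- function() {
  list(
    mwf = c("MO", "PEG", "SO", "SYN", "SSYN"),
    mwf_conc = c(0.05, 0.5, 5),
    solute_conc = c(0.01, 0.05, 0.1, 0.5, 1, 5)
  )
}

.descriptor_cols <- c("E", "S", "A", "B", "V")

#' Load a solute descriptor table
#'
#' Reads a table of Abraham solvation descriptors: `E` (excess molar
#' refractivity), `S` (dipolarity/polarizability), `A` (hydrogen-bond
#' acidity), `B` (hydrogen-bond basicity) and `V` (McGowan characteristic
#' volume). With no `path` the packaged table of the study's 37 solutes is
#' returned.
#'
#' @param path Path to a CSV file with columns `solute_id`, `name`, `E`, `S`,
#'   `A`, `B`, `V`; `NULL` (default) loads the packaged 37-solute table.
#' @return A data frame with one row per solute.
#' @examples
#' desc <- load_solute_table()
#' desc[desc$solute_id == 1, ]
#' @export
load_solute_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "solute_descriptors.csv",
                        package = "mcflfer", mustWork = TRUE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("solute_id", "name", .descriptor_cols)
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L) {
    stop("descriptor table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0L) {
    stop("descriptor table has no rows", call. = FALSE)
  }
  for (col in c("solute_id", .descriptor_cols)) {
    val <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(val) & !is.na(tab[[col]]) & nzchar(tab[[col]]))
    if (length(bad) > 0L || anyNA(val)) {
      row <- if (length(bad) > 0L) bad[1L] else which(is.na(val))[1L]
      stop(sprintf("non-numeric value in column '%s' at data row %d",
                   col, row), call. = FALSE)
    }
    tab[[col]] <- val
  }
  tab$solute_id <- as.integer(tab$solute_id)
  if (anyDuplicated(tab$solute_id)) {
    stop("duplicated solute_id in descriptor table", call. = FALSE)
  }
  if (any(tab$E <= 0) || any(tab$S <= 0) || any(tab$V <= 0) ||
      any(tab$A < 0) || any(tab$B < 0)) {
    stop("descriptor invariant violated: need E, S, V > 0 and A, B >= 0",
         call. = FALSE)
  }
  tab[, required]
}
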