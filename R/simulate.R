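#' Default generating coefficients for the nested model
#'
#' One row per (MWF, MWF concentration) cell with the seven nested-model
#' coefficients: intercept `b0`, descriptor slopes `bE`, `bS`, `bA`, `bB`,
#' `bV`, and the log solute-concentration slope `bt`. The sign pattern
#' emulates the qualitative structure the expanded model is meant to
#' expose: `V` slopes positive (larger molecules partition more), `A` and
#' `B` slopes negative, `S` slopes negative, `E` slopes decreasing with
#' MWF concentration (changing sign within mineral oil), and `bt` negative
#' in 12 of the 15 cells — higher solute concentration depresses the
#' partition coefficient — with exactly three null cells (MO/0.05, PEG/5,
#' SYN/0.05) where the partition theory holds by construction.
#'
#' @return Data frame with columns `mwf`, `mwf_conc`, `b0`, `bE`, `bS`,
#'   `bA`, `bB`, `bV`, `bt`.
#' @export
default_truth_coefficients <- function() {
  tab <- rbind(
    c("MO",   0.05,  0.3,  1.5, -1.4, -1.8, -0.6, 1.8,  0.00),
    c("MO",   0.5,   0.2,  0.3, -0.9, -1.4, -0.9, 1.9, -0.35),
    c("MO",   5,    -0.2, -0.9,  0.3, -1.0, -1.6, 2.2, -0.55),
    c("PEG",  0.05,  0.4,  1.0, -1.0, -1.3, -1.0, 1.7, -0.30),
    c("PEG",  0.5,   0.3,  0.7, -1.0, -1.2, -1.1, 1.7, -0.35),
    c("PEG",  5,     0.2,  0.4, -0.9, -1.2, -1.2, 1.6,  0.00),
    c("SO",   0.05,  0.5,  0.9, -1.2, -1.6, -0.8, 2.0, -0.30),
    c("SO",   0.5,   0.8,  0.4, -0.8, -1.1, -1.0, 1.5, -0.45),
    c("SO",   5,     1.2,  0.0, -0.4, -0.6, -1.0, 0.9, -0.60),
    c("SYN",  0.05,  0.4,  0.8, -1.1, -1.4, -0.9, 2.0,  0.00),
    c("SYN",  0.5,   0.4,  0.6, -1.0, -1.3, -1.0, 1.6, -0.35),
    c("SYN",  5,     0.5,  0.4, -1.0, -1.3, -1.1, 1.2, -0.40),
    c("SSYN", 0.05,  0.4,  0.9, -1.3, -1.5, -0.8, 2.1, -0.30),
    c("SSYN", 0.5,   0.5,  0.5, -0.9, -1.2, -1.0, 1.6, -0.35),
    c("SSYN", 5,     0.7,  0.1, -0.5, -1.0, -1.1, 1.0, -0.50))
  out <- data.frame(mwf = tab[, 1], stringsAsFactors = FALSE)
  num <- c("mwf_conc", "b0", "bE", "bS", "bA", "bB", "bV", "bt")
  for (i in seq_along(num)) out[[num[i]]] <- as.numeric(tab[, i + 1L])
  out
}

#' Configure the synthetic-data generator
#'
#' The generator emulates the study geometry: a chosen set of solutes
#' (descriptors from the packaged table) crossed with the 5 x 3 x 6
#' treatment design, up to `replicates` replicates per combination,
#' responses drawn from the nested LFER model
#' `log10 K = b0 + bE*E + bS*S + bA*A + bB*B + bV*V + bt*log10(conc) + eps`
#' with `eps ~ Normal(0, noise_sd^2)`, and independent Bernoulli dropout of
#' replicates. The default dropout 0.535 reproduces the study's observed
#' retention (4646 of the 9990 possible observations, about 46.5 percent).
#'
#' @param solute_ids Solutes to include (default all 37).
#' @param descriptors Descriptor table, default [load_solute_table()].
#' @param mwfs,mwf_concs,solute_concs Level sets, default the study design.
#' @param replicates Replicates per combination, default 3.
#' @param coefficients Per-cell generating coefficients, default
#'   [default_truth_coefficients()]; must cover every (mwf, mwf_conc) cell.
#' @param noise_sd Gaussian error SD on the log10 scale, default 0.25.
#' @param dropout Probability a replicate is missing, default 0.535.
#' @param seed Optional integer seed stored in the config;
#'   [generate_observations()] requires a seed here or as an argument.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(solute_ids = 1:37,
                             descriptors = load_solute_table(),
                             mwfs = study_levels()$mwf,
                             mwf_concs = study_levels()$mwf_conc,
                             solute_concs = study_levels()$solute_conc,
                             replicates = 3L,
                             coefficients = default_truth_coefficients(),
                             noise_sd = 0.25,
                             dropout = 0.535,
                             seed = NULL) {
  solute_ids <- as.integer(unlist(solute_ids))
  mwfs <- as.character(unlist(mwfs))
  mwf_concs <- as.numeric(unlist(mwf_concs))
  solute_concs <- as.numeric(unlist(solute_concs))
  if (!all(solute_ids %in% descriptors$solute_id)) {
    stop("solute_ids missing from the descriptor table", call. = FALSE)
  }
  if (dropout < 0 || dropout >= 1) stop("need 0 <= dropout < 1",
                                        call. = FALSE)
  if (noise_sd < 0) stop("need noise_sd >= 0", call. = FALSE)
  if (replicates < 1L) stop("need replicates >= 1", call. = FALSE)
  want <- paste(rep(mwfs, each = length(mwf_concs)),
                .fmt_num(mwf_concs), sep = "/")
  have <- mwf_cell_id(coefficients$mwf, coefficients$mwf_conc)
  miss <- setdiff(want, have)
  if (length(miss) > 0L) {
    stop("coefficient table missing cell(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  structure(list(
    solute_ids = as.integer(solute_ids),
    descriptors = descriptors,
    mwfs = mwfs, mwf_concs = mwf_concs, solute_concs = solute_concs,
    replicates = as.integer(replicates),
    coefficients = coefficients,
    noise_sd = noise_sd,
    dropout = dropout,
    seed = seed
  ), class = "generator_config")
}

#' Default generator configuration
#'
#' The study-calibrated generator truth: all 37 solutes, the full 90-cell
#' design, 3 replicates, [default_truth_coefficients()], `noise_sd = 0.25`
#' and `dropout = 0.535`.
#'
#' @return A `generator_config`.
#' @export
default_truth <- function() generator_config()

#' Read a generator configuration from YAML
#'
#' Recognised top-level keys mirror the [generator_config()] arguments;
#' `coefficients` may be given as a list of per-cell records with fields
#' `mwf`, `mwf_conc`, `b0`, `bE`, `bS`, `bA`, `bB`, `bV`, `bt`. Omitted
#' keys fall back to the defaults.
#'
#' @param path YAML file path.
#' @return A `generator_config`.
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  for (key in c("solute_ids", "mwfs", "mwf_concs", "solute_concs",
                "replicates", "noise_sd", "dropout", "seed")) {
    if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
  }
  if (!is.null(raw$coefficients)) {
    args$coefficients <- do.call(rbind, lapply(raw$coefficients,
                                               as.data.frame))
  }
  do.call(generator_config, args)
}

#' Generate a synthetic observation set
#'
#' Draws one dataset from the configured generating model. The draw is
#' deterministic in `(config, seed)`: identical inputs give byte-identical
#' output tables.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; overrides `config$seed`. Required.
#' @return A list with `observations` (an [observation_set()]) and `truth`
#'   (the coefficients used, the seed, realised row count and per-cell
#'   realised counts).
#' @export
generate_observations <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(seed)) {
    stop("a seed is required: pass seed= or set it in the config",
         call. = FALSE)
  }
  grid <- expand.grid(replicate = seq_len(config$replicates),
                      solute_conc = config$solute_concs,
                      mwf_conc = config$mwf_concs,
                      mwf = config$mwfs,
                      solute_id = config$solute_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  co <- config$coefficients
  ci <- match(mwf_cell_id(grid$mwf, grid$mwf_conc),
              mwf_cell_id(co$mwf, co$mwf_conc))
  desc <- config$descriptors
  di <- match(grid$solute_id, desc$solute_id)
  mu <- co$b0[ci] +
    co$bE[ci] * desc$E[di] + co$bS[ci] * desc$S[di] +
    co$bA[ci] * desc$A[di] + co$bB[ci] * desc$B[di] +
    co$bV[ci] * desc$V[di] +
    co$bt[ci] * log10(grid$solute_conc)
  set.seed(as.integer(seed))
  keep <- stats::runif(nrow(grid)) >= config$dropout
  eps <- stats::rnorm(sum(keep), 0, config$noise_sd)
  out <- grid[keep, , drop = FALSE]
  out$log_k <- mu[keep] + eps
  obs <- observation_set(out, descriptors = desc,
                         levels = list(mwf = config$mwfs,
                                       mwf_conc = config$mwf_concs,
                                       solute_conc = config$solute_concs),
                         permissive = FALSE)
  counts <- table(mwf_cell_id(out$mwf, out$mwf_conc))
  list(observations = obs,
       truth = list(coefficients = co, seed = as.integer(seed),
                    n_rows = nrow(out), cell_counts = counts,
                    noise_sd = config$noise_sd,
                    dropout = config$dropout))
}

# long view of a generating-coefficient table keyed like nested design columns
.truth_long <- function(coefficients) {
  descs <- c("(Intercept)", "E", "S", "A", "B", "V", "t")
  cols <- c("b0", "bE", "bS", "bA", "bB", "bV", "bt")
  out <- lapply(seq_len(nrow(coefficients)), function(r) {
    cell <- mwf_cell_id(coefficients$mwf[r], coefficients$mwf_conc[r])
    data.frame(cell = cell, descriptor = descs,
               column = paste(cell, descs, sep = ":"),
               true = as.numeric(coefficients[r, cols]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Parameter-recovery study for the nested model
#'
#' Repeats generate-then-fit `n_reps` times and summarises, per nested
#' coefficient, the bias, root-mean-square error and empirical coverage of
#' the fit's confidence intervals against the generating truth.
#'
#' @param config A [generator_config()].
#' @param n_reps Number of generate/fit cycles.
#' @param seed Base seed; cycle `r` uses `seed + r - 1`.
#' @param ci_level CI level whose coverage is tracked, default 0.95.
#' @return Data frame with one row per coefficient: `cell`, `descriptor`,
#'   `true`, `bias`, `rmse`, `coverage`, `n_fits`.
#' @export
recovery_study <- function(config, n_reps, seed = config$seed,
                           ci_level = 0.95) {
  stopifnot(inherits(config, "generator_config"), n_reps >= 1L)
  if (is.null(seed)) stop("a base seed is required", call. = FALSE)
  co <- config$coefficients
  in_design <- co$mwf %in% config$mwfs &
    .num_in(co$mwf_conc, config$mwf_concs)
  truth <- .truth_long(co[in_design, , drop = FALSE])
  est <- matrix(NA_real_, nrow(truth), n_reps,
                dimnames = list(truth$column, NULL))
  cover <- matrix(NA, nrow(truth), n_reps)
  for (r in seq_len(n_reps)) {
    sim <- generate_observations(config, seed = as.integer(seed) + r - 1L)
    fit <- fit_lfer(sim$observations, "nested", ci_level = ci_level)
    idx <- match(truth$column, names(fit$coefficients))
    est[, r] <- fit$coefficients[idx]
    cover[, r] <- fit$ci_low[idx] <= truth$true &
      truth$true <= fit$ci_high[idx]
  }
  err <- est - truth$true
  data.frame(
    cell = truth$cell,
    descriptor = truth$descriptor,
    true = truth$true,
    bias = rowMeans(err, na.rm = TRUE),
    rmse = sqrt(rowMeans(err^2, na.rm = TRUE)),
    coverage = rowMeans(cover, na.rm = TRUE),
    n_fits = rowSums(!is.na(est)),
    stringsAsFactors = FALSE)
}
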