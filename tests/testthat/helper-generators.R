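# small generator configurations used across tests

# a reduced design: few solutes / cells so brute-force refits stay cheap
small_config <- function(n_solutes = 10, mwfs = c("MO", "SO"),
                         mwf_concs = c(0.05, 5),
                         solute_concs = c(0.01, 0.1, 1),
                         replicates = 1L, noise_sd = 0.25, dropout = 0,
                         coefficients = default_truth_coefficients(),
                         seed = NULL) {
  generator_config(solute_ids = seq_len(n_solutes), mwfs = mwfs,
                   mwf_concs = mwf_concs, solute_concs = solute_concs,
                   replicates = replicates, coefficients = coefficients,
                   noise_sd = noise_sd, dropout = dropout, seed = seed)
}

.num_in_test <- function(x, value, tol = 1e-9) abs(x - value) < tol

# three replicates of a single solute in a single treatment cell; within
# that cell every predictor is constant, so the fit is intercept-only
constant_cell_obs <- function(log_k = c(1, 2, 3)) {
  observation_set(data.frame(
    solute_id = 1L, mwf = "MO", mwf_conc = 0.05, solute_conc = 1,
    replicate = seq_along(log_k), log_k = log_k))
}
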