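test_that("with a single cell the F statistic is the squared t statistic", {
  cfg <- small_config(n_solutes = 15, mwfs = "MO", mwf_concs = 0.5,
                      solute_concs = c(0.01, 0.1, 1, 5), replicates = 2L,
                      noise_sd = 0.3)
  sim <- generate_observations(cfg, seed = 201)
  glob <- test_partition_global(sim$observations)
  cells <- test_partition_cells(sim$observations)
  expect_equal(glob$df[1], 1L)
  expect_equal(glob$f, cells$per_cell$t^2, tolerance = 1e-10)
  expect_equal(glob$p_value, cells$per_cell$p_value, tolerance = 1e-10)
})

test_that("single-concentration data cannot test the theory", {
  cfg <- small_config(solute_concs = 1, replicates = 2L)
  sim <- generate_observations(cfg, seed = 211)
  expect_error(test_partition_global(sim$observations), "degenerate")
})

test_that("per-cell tests use the Bonferroni threshold over the design", {
  sim <- generate_observations(default_truth(), seed = 221)
  cells <- test_partition_cells(sim$observations, alpha = 0.05)
  expect_equal(cells$bonferroni_divisor, 15L)
  expect_equal(cells$threshold, 0.05 / 15)
  expect_equal(cells$n_cells_tested, 15L)
  expect_equal(cells$per_cell$significant,
               cells$per_cell$p_value < 0.05 / 15)
  expect_equal(sum(cells$per_cell$n_obs), nrow(sim$observations$observations))

  tested <- test_partition_cells(sim$observations, divisor = "tested")
  expect_equal(tested$bonferroni_divisor, 15L) # all 15 estimable here
})

test_that("cells with one concentration level are reported unestimable", {
  sim <- generate_observations(default_truth(), seed = 231)
  rows <- sim$observations$observations
  keep <- !(rows$mwf == "MO" & rows$mwf_conc == 0.05) |
    .num_in_test(rows$solute_conc, 0.1)
  obs <- observation_set(rows[keep, ],
                         descriptors = sim$observations$descriptors)
  cells <- test_partition_cells(obs)
  expect_equal(cells$unestimable, "MO/0.05")
  expect_equal(cells$n_cells_tested, 14L)
  expect_equal(cells$bonferroni_divisor, 15L) # fixed at the design size
  expect_equal(test_partition_cells(obs,
                                    divisor = "tested")$bonferroni_divisor,
               14L)
})

test_that("global p-value is invariant to row order and solute relabeling", {
  sim <- generate_observations(small_config(noise_sd = 0.3,
                                            replicates = 2L), seed = 241)
  obs <- sim$observations
  p0 <- test_partition_global(obs)$p_value
  perm <- observation_set(obs$observations[sample(120), ],
                          descriptors = obs$descriptors)
  expect_equal(test_partition_global(perm)$p_value, p0, tolerance = 1e-10)

  relab <- obs$observations
  map <- 30:21 # new identities, descriptor values stay attached
  desc <- obs$descriptors[1:10, ]
  desc$solute_id <- map
  relab$solute_id <- map[relab$solute_id]
  relabeled <- observation_set(relab, descriptors = desc)
  expect_equal(test_partition_global(relabeled)$p_value, p0,
               tolerance = 1e-10)
})

test_that("subset battery reruns the tests per concentration subset", {
  sim <- generate_observations(generator_config(dropout = 0.3), seed = 251)
  res <- subset_analysis(sim$observations)
  expect_equal(nrow(res$table), 7L)
  expect_equal(res$table$subset[1], "All")
  expect_true(all(res$table$global_p < 1e-4)) # strong slopes everywhere
  expect_true(all(nzchar(res$table$significant_cells)))

  expect_error(subset_analysis(sim$observations, subsets = list(one = 5)),
               "at least 2")
})

test_that("null-slope generator keeps the global test near its level", {
  co <- default_truth_coefficients()
  co$bt <- 0
  cfg <- small_config(n_solutes = 20, replicates = 2L, noise_sd = 0.25,
                      coefficients = co)
  p <- vapply(1:60, function(s) {
    sim <- generate_observations(cfg, seed = 300 + s)
    test_partition_global(sim$observations)$p_value
  }, 0)
  rate <- mean(p < 0.05)
  expect_gte(rate, 0)     # sanity
  expect_lt(rate, 0.17)   # 60 draws at level 0.05: P(>=10 rejections) < 1e-3
  expect_gt(min(p), 0)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})
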