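test_that("intercept-only worked example gives Q2_LOO = -1.25", {
  # single solute, single cell, responses 1,2,3: every predictor is
  # constant so the fit is a mean. Leave-one-out enumerated by hand:
  # predictions (2.5, 2, 1.5), PRESS = 1.5^2 + 0 + 1.5^2 = 4.5,
  # denominator = (1-2)^2 + 0 + (3-2)^2 = 2, Q2 = 1 - 4.5/2 = -1.25.
  obs <- constant_cell_obs(c(1, 2, 3))
  for (m in c("hat", "refit")) {
    cv <- q2_loo(obs, "nested", method = m)
    expect_equal(cv$q2, -1.25, tolerance = 1e-12)
    expect_equal(cv$press, 4.5, tolerance = 1e-12)
    expect_equal(cv$n_unpredictable, 0L)
  }
})

test_that("hat-matrix identity agrees with brute-force refits", {
  cfg <- small_config(n_solutes = 9, mwfs = "MO", mwf_concs = c(0.05, 5),
                      solute_concs = c(0.01, 0.1, 1), replicates = 1L,
                      noise_sd = 0.3)
  sim <- generate_observations(cfg, seed = 101)
  obs <- sim$observations # 9 x 2 x 3 = 54 rows
  for (variant in c("single", "nested")) {
    a <- q2_loo(obs, variant, method = "hat")
    b <- q2_loo(obs, variant, method = "refit")
    expect_equal(a$q2, b$q2, tolerance = 1e-8)
    expect_equal(a$press, b$press, tolerance = 1e-8)
  }
})

test_that("with one row per solute, LOSO and LOO coincide", {
  cfg <- small_config(n_solutes = 14, mwfs = "MO", mwf_concs = 0.05,
                      solute_concs = 0.1, replicates = 1L, noise_sd = 0.4)
  sim <- generate_observations(cfg, seed = 111)
  obs <- sim$observations
  expect_equal(table(obs$observations$solute_id),
               table(obs$observations$solute_id) * 0 + 1,
               ignore_attr = TRUE)
  loo <- q2_loo(obs, "single", method = "refit")
  loso <- q2_loso(obs, "single")
  expect_equal(loso$q2, loo$q2, tolerance = 1e-10)
})

test_that("duplicating rows inflates Q2_LOO but not Q2_LOSO", {
  cfg <- small_config(n_solutes = 10, noise_sd = 0.4)
  sim <- generate_observations(cfg, seed = 121)
  obs <- sim$observations
  rows <- obs$observations
  dup_rows <- rbind(rows, transform(rows, replicate = replicate + 3L))
  dup <- observation_set(dup_rows, descriptors = obs$descriptors)

  loo0 <- q2_loo(obs, "nested")
  loo1 <- q2_loo(dup, "nested")
  loso0 <- q2_loso(obs, "nested")
  loso1 <- q2_loso(dup, "nested")
  r2 <- fit_lfer(dup, "nested")$r2

  # the held-out row's twin stays in the training fold, dragging the
  # deleted prediction toward the observation
  expect_gt(loo1$q2, loo0$q2)
  expect_lt(abs(loo1$q2 - r2), abs(loo0$q2 - r2))
  # leaving out the whole solute removes both copies: numerator and
  # denominator double, the statistic is unchanged
  expect_equal(loso1$q2, loso0$q2, tolerance = 1e-10)
})

test_that("noiseless data scores Q2 = 1 on both statistics", {
  sim <- generate_observations(small_config(noise_sd = 0, replicates = 2),
                               seed = 131)
  expect_equal(q2_loo(sim$observations, "nested")$q2, 1, tolerance = 1e-8)
  expect_equal(q2_loso(sim$observations, "nested")$q2, 1, tolerance = 1e-8)
})

test_that("Q2_LOO never exceeds r2 and is order-invariant", {
  for (seed in 1:4) {
    sim <- generate_observations(small_config(noise_sd = 0.5),
                                 seed = 140 + seed)
    obs <- sim$observations
    fit <- fit_lfer(obs, "nested")
    loo <- q2_loo(obs, "nested")
    expect_lte(loo$q2, fit$r2 + 1e-10)

    perm <- observation_set(
      obs$observations[sample(nrow(obs$observations)), ],
      descriptors = obs$descriptors)
    expect_equal(q2_loo(perm, "nested")$q2, loo$q2, tolerance = 1e-10)
    expect_equal(q2_loso(perm, "nested")$q2, q2_loso(obs, "nested")$q2,
                 tolerance = 1e-10)
  }
})

test_that("constant responses make Q2 undefined", {
  obs <- constant_cell_obs(c(2, 2, 2))
  expect_error(q2_loo(obs, "nested"), "undefined")
})

test_that("fit statistics table has one row per variant", {
  sim <- generate_observations(small_config(n_solutes = 12,
                                            replicates = 2,
                                            noise_sd = 0.25), seed = 151)
  tab <- fit_statistics_table(sim$observations)
  expect_equal(tab$model, c("single", "crossed", "nested"))
  expect_true(all(c("r2", "adj_r2", "q2_loo", "q2_loso") %in% names(tab)))
  expect_true(all(tab$q2_loso <= 1))

  noiseless <- generate_observations(
    small_config(n_solutes = 12, replicates = 2, noise_sd = 0), seed = 152)
  row_nested <- fit_statistics_table(noiseless$observations,
                                     variants = "nested")
  expect_equal(unlist(row_nested[, c("r2", "adj_r2", "q2_loo", "q2_loso")],
                      use.names = FALSE),
               rep(1, 4), tolerance = 1e-8)
})
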