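test_that("noiseless linear data is fitted exactly", {
  sim <- generate_observations(small_config(noise_sd = 0, replicates = 2),
                               seed = 21)
  fit <- fit_lfer(sim$observations, "nested")
  expect_lt(max(abs(fit$residuals)), 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
})

test_that("crossed-model estimates equal independent per-cell lm fits", {
  sim <- generate_observations(generator_config(solute_ids = 1:20,
                                                dropout = 0,
                                                replicates = 1),
                               seed = 31)
  obs <- sim$observations
  fit <- fit_lfer(obs, "crossed")
  rows <- obs$observations
  desc <- obs$descriptors
  dat <- cbind(rows, desc[match(rows$solute_id, desc$solute_id),
                          c("E", "S", "A", "B", "V")])
  dat$cell <- cell_id(dat$mwf, dat$mwf_conc, dat$solute_conc)
  for (cl in sample(unique(dat$cell), 12)) {
    oracle <- lm(log_k ~ E + S + A + B + V, data = dat[dat$cell == cl, ])
    ours <- fit$coefficients[paste0(
      cl, ":", c("(Intercept)", "E", "S", "A", "B", "V"))]
    expect_equal(unname(ours), unname(coef(oracle)), tolerance = 1e-8)
  }
})

test_that("intercept-only fit gives the mean with zero r2", {
  d <- structure(list(
    X = matrix(1, 3, 1, dimnames = list(NULL, "(Intercept)")),
    col_meta = data.frame(column = "(Intercept)",
                          descriptor = "(Intercept)",
                          cell = NA_character_),
    row_meta = data.frame(solute_id = 1L, mwf = "MO", mwf_conc = 0.05,
                          solute_conc = 1, replicate = 1:3,
                          cell = NA_character_),
    y = c(1, 2, 3), variant = "single", include_t = TRUE),
    class = "lfer_design")
  fit <- fit_ols(d)
  expect_equal(unname(fit$coefficients), 2)
  expect_equal(fit$r2, 0)
  expect_equal(fit$df_resid, 2L)
  expect_equal(unname(fit$se), sqrt(1 / 3)) # sigma2 = 1, diag (X'X)^-1 = 1/3
})

test_that("adding a constant shifts only the intercepts", {
  sim <- generate_observations(small_config(), seed = 41)
  obs <- sim$observations
  f0 <- fit_lfer(obs, "nested")
  shifted <- obs$observations
  shifted$log_k <- shifted$log_k + 2.5
  f1 <- fit_lfer(observation_set(shifted, descriptors = obs$descriptors),
                 "nested")
  is_int <- f0$col_meta$descriptor == "(Intercept)"
  expect_equal(f1$coefficients[is_int], f0$coefficients[is_int] + 2.5,
               tolerance = 1e-10)
  expect_equal(f1$coefficients[!is_int], f0$coefficients[!is_int],
               tolerance = 1e-10)
})

test_that("adjusted r2 never exceeds r2", {
  for (seed in 1:5) {
    sim <- generate_observations(small_config(noise_sd = 0.5), seed = seed)
    fit <- fit_lfer(sim$observations, "nested")
    expect_lte(fit$adj_r2, fit$r2)
  }
})

test_that("confidence intervals bracket the estimates", {
  sim <- generate_observations(small_config(), seed = 51)
  fit <- fit_lfer(sim$observations, "crossed")
  kept <- !is.na(fit$coefficients)
  expect_true(all(fit$ci_low[kept] < fit$coefficients[kept]))
  expect_true(all(fit$coefficients[kept] < fit$ci_high[kept]))
  tab <- coef_table(fit)
  expect_equal(names(tab), c("cell", "descriptor", "estimate", "se",
                             "ci_low", "ci_high"))
})

test_that("per-cell fits recover generating coefficients and skip small cells", {
  # crossed generator: within one (i,j) cell the nested truth with a fixed
  # concentration is a plain single-LFER truth per crossed cell
  cfg <- generator_config(dropout = 0, noise_sd = 0.1)
  sim <- generate_observations(cfg, seed = 61)
  pc <- fit_per_cell(sim$observations)
  expect_equal(length(pc$fits) + nrow(pc$skipped), 90L)
  expect_equal(nrow(pc$skipped), 0L)

  co <- cfg$coefficients
  for (cl in c("MO/0.05/0.01", "SO/5/5")) {
    f <- pc$fits[[cl]]
    parts <- strsplit(cl, "/")[[1]]
    tr <- co[co$mwf == parts[1] & co$mwf_conc == as.numeric(parts[2]), ]
    truth <- c(tr$b0 + tr$bt * log10(as.numeric(parts[3])),
               tr$bE, tr$bS, tr$bA, tr$bB, tr$bV)
    kept <- !is.na(f$coefficients)
    expect_true(all(abs(f$coefficients[kept] - truth[kept]) /
                      f$se[kept] < 4))
  }

  # a cell with six rows has no residual df for the six-parameter model
  rows <- sim$observations$observations
  one_cell <- rows[cell_id(rows$mwf, rows$mwf_conc, rows$solute_conc) ==
                     "MO/0.05/0.01", ][1:6, ]
  pc_small <- fit_per_cell(observation_set(one_cell))
  expect_equal(nrow(pc_small$skipped), 1L)
  expect_match(pc_small$skipped$reason, "insufficient df")

  tab <- per_cell_coef_table(pc)
  expect_equal(nrow(tab), 90L * 6L)
})

test_that("predictions match the coefficient dot product", {
  sim <- generate_observations(small_config(), seed = 71)
  obs <- sim$observations
  fit <- fit_lfer(obs, "nested")
  # training rows reproduce fitted values
  expect_equal(predict_lfer(fit, obs), fit$fitted, tolerance = 1e-10)

  row1 <- obs$observations[1, , drop = FALSE]
  new1 <- observation_set(row1, descriptors = obs$descriptors)
  d <- obs$descriptors[obs$descriptors$solute_id == row1$solute_id, ]
  beta <- fit$coefficients[paste0(
    mwf_cell_id(row1$mwf, row1$mwf_conc), ":",
    c("(Intercept)", "E", "S", "A", "B", "V", "t"))]
  by_hand <- sum(beta * c(1, d$E, d$S, d$A, d$B, d$V,
                          log10(row1$solute_conc)))
  expect_equal(predict_lfer(fit, new1), by_hand, tolerance = 1e-10)
})

test_that("a solute absent from training is still predictable", {
  sim <- generate_observations(small_config(n_solutes = 12), seed = 81)
  rows <- sim$observations$observations
  train <- observation_set(rows[rows$solute_id != 3, ])
  test <- observation_set(rows[rows$solute_id == 3, ])
  fit <- fit_lfer(train, "nested")
  expect_true(all(is.finite(predict_lfer(fit, test))))
})

test_that("predictions into absent blocks are flagged NA", {
  sim <- generate_observations(small_config(), seed = 91)
  rows <- sim$observations$observations
  train <- observation_set(rows[rows$mwf != "SO", ])
  test_so <- observation_set(rows[rows$mwf == "SO", ])
  fit <- fit_lfer(train, "nested")
  expect_true(all(is.na(predict_lfer(fit, test_so))))
})
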