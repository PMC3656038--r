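test_that("depth harmonisation applies the layer coefficients monotonically", {
  expect_equal(soc_to_30cm(10, "0-30"), 10)
  expect_equal(soc_to_30cm(10, "0-20"), 13.2)
  expect_equal(soc_to_30cm(10, "0-10"), 23.5)
  expect_equal(soc_to_30cm(c(1, 1, 1), c("0-10", "0-20", "0-30")),
               c(2.35, 1.32, 1))
  # the shallower the layer, the larger the converted value
  v <- soc_to_30cm(rep(8, 3), c("0-10", "0-20", "0-30"))
  expect_true(all(diff(v) < 0))
  expect_error(soc_to_30cm(10, "0-50"), "unsupported depth")
  expect_error(soc_to_30cm(-1, "0-30"), "non-negative")
})

test_that("evaluation statistics reproduce hand-computed cases", {
  P <- c(2, 4); O <- c(1, 3)
  expect_equal(mean_deviation(P, O), 1)
  expect_equal(mean_deviation(O, P), -1)  # antisymmetry
  expect_equal(rmse(P, O), 1)
  expect_equal(rmd(P, O), 50)
  O2 <- c(1, 2, 4)
  expect_equal(mean_deviation(O2, O2), 0)
  expect_equal(rmse(O2, O2), 0)
  expect_equal(rmd(O2, O2), 0)
  expect_equal(model_efficiency(O2, O2), 1)
  # predicting the observed mean gives EF = 0
  expect_equal(model_efficiency(rep(mean(O2), 3), O2), 0)
  expect_lte(model_efficiency(c(9, 9, 9), O2), 1)
  expect_equal(rmse(P, O, normalized = TRUE), 100 / 2 * 1)
  expect_error(model_efficiency(c(1, 1), c(2, 2)), "constant")
  expect_error(mean_deviation(1:3, 1:4), "equal length")
})

test_that("regression evaluation tests slope=1 and intercept=0 sensibly", {
  O <- seq(10, 40, length.out = 12)
  # identity input triggers lm's perfect-fit warning; the estimates are exact
  r_id <- suppressWarnings(regression_eval(O, O))
  expect_equal(r_id$slope, 1)
  expect_equal(r_id$intercept, 0, tolerance = 1e-10)
  expect_equal(r_id$r_squared, 1)
  set.seed(7)
  noisy <- O + rnorm(12, 0, 0.5)
  r1 <- regression_eval(noisy, O)
  expect_false(r1$slope_differs_from_1)
  r2 <- regression_eval(2 * O + rnorm(12, 0, 0.5), O)
  expect_true(r2$slope_differs_from_1)
  expect_gt(r2$slope, 1.8)
  # r-squared is invariant to affine rescaling of both series
  ra <- regression_eval(noisy, O)
  rb <- regression_eval(3 * noisy + 5, 2 * O - 7)
  expect_equal(ra$r_squared, rb$r_squared, tolerance = 1e-10)
  expect_error(regression_eval(c(1, 2, 3), c(2, 2, 2)), "zero variance")
})

# Calibration fixture: four 50-year trials with annual SOC sampling -- a
# low-input site, a high-input site, a drier site (reduced environmental
# modifier) and a bare fallow. The fallow isolates the pool kinetics and the
# contrasting inputs/modifier split the rate-vs-fraction trade-offs, which a
# single cropped treatment cannot do.
make_recovery_trials <- function(truth, cv, seeds) {
  sp <- function(...) synthetic_spec(n_years = 50L, soc_obs_cv = cv, ...)
  list(
    gen_site_trial(sp(), truth, initial_soc = 20, retention = 0.705,
                   obs_every = 1, seed = seeds[1]),
    gen_site_trial(sp(), truth, initial_soc = 40, retention = 0.95,
                   obs_every = 1, seed = seeds[2]),
    gen_site_trial(sp(), truth, initial_soc = 30, retention = 0.83,
                   obs_every = 1, f_env = 0.6, seed = seeds[3]),
    gen_site_trial(sp(yield_start = 0), truth, initial_soc = 30,
                   retention = 0.83, obs_every = 1, seed = seeds[4]))
}

recovery_grid <- function() {
  search_spec(K_LC = c(2.0e-4, 2.5e-4, 3.0e-4),
              K_HC = c(2.0e-5, 2.6e-5, 3.2e-5),
              F_LL = c(0.2, 0.3, 0.4),
              F_RL = c(0.35, 0.45, 0.55),
              F_LH = c(0.2, 0.3, 0.4))
}

test_that("grid search recovers on-grid generating parameters", {
  truth <- soc_params()  # on every default-style grid below
  spec_grid <- recovery_grid()
  trials <- make_recovery_trials(truth, cv = 0.01, seeds = 101:104)
  fit <- grid_search_calibrate(spec_grid, trials)
  for (nm in c("K_LC", "K_HC", "F_LL", "F_RL", "F_LH"))
    expect_equal(fit$params[[nm]], truth[[nm]])
  expect_lt(fit$objective, 0.5)
  # single-point grid returns that point
  single <- search_spec(K_LC = 2.5e-4, K_HC = 2.6e-5, F_LL = 0.3,
                        F_RL = 0.45, F_LH = 0.3)
  fit1 <- grid_search_calibrate(single, trials)
  expect_equal(nrow(fit1$grid), 1)
  expect_equal(fit1$params$K_HC, 2.6e-5)
  # shrinking a range around the optimum never worsens the objective
  shrunk <- search_spec(K_LC = 2.5e-4, K_HC = c(2.0e-5, 2.6e-5, 3.2e-5),
                        F_LL = 0.3, F_RL = 0.45, F_LH = c(0.2, 0.3, 0.4))
  fit_s <- grid_search_calibrate(shrunk, trials)
  expect_lte(fit_s$objective, fit$objective + 1e-12)
  expect_error(grid_search_calibrate(spec_grid, list()), "non-empty")
})
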