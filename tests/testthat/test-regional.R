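make_test_region <- function(n_cells = 4, n_years = 20, soc = NULL,
                             area = 2, yield0 = 1.2) {
  if (is.null(soc)) soc <- seq(24, 36, length.out = n_cells)
  region_inputs(
    name = "TEST", area_Mha = area,
    soil = data.frame(cell_id = seq_along(soc), soc_Mg_ha = soc),
    yields = data.frame(year = 1960 + seq_len(n_years) - 1,
                        yield_Mg_per_ha = rep(yield0, n_years)),
    retention = 0.83)
}

test_that("soil-state sampling follows the empirical grid distribution", {
  one <- data.frame(cell_id = 1, soc_Mg_ha = 31)
  expect_equal(sample_soil_state(one, 5)$soc_Mg_ha, rep(31, 5))
  grid <- data.frame(cell_id = 1:4, soc_Mg_ha = c(10, 20, 30, 40))
  set.seed(99)
  draws <- sample_soil_state(grid, 1e4)$soc_Mg_ha
  counts <- table(draws)
  expect_length(counts, 4)
  # 3-sigma binomial band around 2500 each
  expect_true(all(abs(counts - 2500) < 3 * sqrt(1e4 * 0.25 * 0.75)))
  set.seed(5); a <- sample_soil_state(grid, 10)
  set.seed(5); b <- sample_soil_state(grid, 10)
  expect_identical(a, b)
  expect_error(sample_soil_state(grid[0, ]), "empty")
})

test_that("input-scale draws are uniform on the stated support", {
  expect_equal(sample_input_scale(3, 0), rep(1, 3))
  set.seed(21)
  d <- sample_input_scale(1e5, 0.1)
  expect_true(all(d >= 0.9 & d <= 1.1))
  expect_equal(mean(d), 1, tolerance = 1e-3)
  expect_error(sample_input_scale(5, 1), "halfwidth")
})

test_that("run_region is deterministic, and zero yield gives pure decay", {
  rg <- make_test_region()
  a <- run_region(rg, spin_up_years = 10)
  b <- run_region(rg, spin_up_years = 10)
  expect_identical(a, b)
  expect_length(a$soc, 21)
  expect_equal(a$soc[1], mean(rg$soil$soc_Mg_ha))
  rg0 <- make_test_region(yield0 = 0)
  d <- run_region(rg0, spin_up_years = 0)
  expect_true(all(diff(d$soc) < 0))
})

test_that("decadal accounting telescopes and respects the Mg/ha x Mha = Tg identity", {
  # a 6.4 Mg/ha drop over one decade on 10 Mha is -64 Tg
  soc <- c(seq(30, 23.6, length.out = 11), seq(23.4, 22, length.out = 10))
  years <- 1960:1980
  s <- decadal_summary(soc, years, c_input = rep(1, 20), area_Mha = 10,
                       name = "X")
  expect_equal(s$decades$change_Tg[1], -64, tolerance = 1e-9)
  expect_equal(sum(s$decades$change_Tg), s$total_change_Tg)
  expect_equal(s$total_change_Tg, (soc[21] - soc[1]) * 10, tolerance = 1e-9)
  # flat series: zero change everywhere
  flat <- decadal_summary(rep(25, 21), years, rep(1, 20), 10)
  expect_equal(flat$decades$change_Tg, c(0, 0))
  expect_error(decadal_summary(rep(25, 16), 1960:1975, rep(1, 15), 10),
               "whole decades")
  # doubling the area doubles stocks, leaves densities unchanged
  s2 <- decadal_summary(soc, years, rep(1, 20), 20)
  expect_equal(s2$decades$change_Tg, 2 * s$decades$change_Tg)
  expect_equal(s2$decades$density, s$decades$density)
})

test_that("a degenerate ensemble collapses onto the deterministic run", {
  rg <- make_test_region(n_cells = 1, soc = 30)
  det <- run_region(rg, spin_up_years = 10)
  mc <- monte_carlo_region(rg, cfg = mc_config(n_runs = 8, input_halfwidth = 0,
                                               seed = 1),
                           spin_up_years = 10)
  expect_equal(mc$lo, mc$hi)
  expect_equal(mc$mean, det$soc, tolerance = 1e-14)
  expect_equal(unname(mc$soc[1, ]), det$soc, tolerance = 1e-14)
})

test_that("Monte Carlo ensembles are seed-reproducible and cover the mean run", {
  rg <- make_test_region(n_cells = 1, soc = 30, n_years = 20)
  cfg <- mc_config(n_runs = 60, input_halfwidth = 0.1, seed = 42)
  mc1 <- monte_carlo_region(rg, cfg = cfg, spin_up_years = 5)
  mc2 <- monte_carlo_region(rg, cfg = cfg, spin_up_years = 5)
  expect_identical(mc1, mc2)
  det <- run_region(rg, spin_up_years = 5)
  final_mean <- det$soc[length(det$soc)]
  expect_gte(final_mean, mc1$lo[length(mc1$lo)])
  expect_lte(final_mean, mc1$hi[length(mc1$hi)])
  expect_error(mc_config(n_runs = 0), "n_runs")
})

printed_summary <- function(name, area, initial, density, input, change) {
  structure(list(region = name, area_Mha = area, initial_density = initial,
                 decades = data.frame(
                   decade = paste0(seq(1960, by = 10,
                                       length.out = length(change)), "s"),
                   density = density, input = input, change_Tg = change,
                   stringsAsFactors = FALSE),
                 total_change_Tg = sum(change)),
            class = "regional_summary")
}

test_that("belt aggregation sums areas/stocks and area-weights densities", {
  s1 <- printed_summary("A", 2, 30, c(28, 26), c(1, 1.2), c(-10, -6))
  s2 <- printed_summary("B", 6, 24, c(23, 22), c(0.8, 0.9), c(-12, -3))
  belt <- aggregate_belt(list(s1, s2))
  expect_equal(belt$area_Mha, 8)
  expect_equal(belt$decades$change_Tg, c(-22, -9))
  expect_equal(belt$total_change_Tg, -31)
  expect_equal(belt$decades$density, (2 * c(28, 26) + 6 * c(23, 22)) / 8)
  expect_equal(belt$initial_density, (2 * 30 + 6 * 24) / 8)
  # single region aggregates to itself
  solo <- aggregate_belt(list(s1), name = "A")
  expect_equal(solo$decades$change_Tg, s1$decades$change_Tg)
  expect_equal(solo$initial_density, s1$initial_density)
  expect_error(aggregate_belt(list(s1, s1)), "duplicate")
  # permutation invariance
  belt_rev <- aggregate_belt(list(s2, s1))
  expect_equal(belt_rev$total_change_Tg, belt$total_change_Tg)
  expect_equal(belt_rev$decades$density, belt$decades$density)
})

test_that("loss rates and shares convert decadal stocks correctly", {
  s <- printed_summary("X", 10, 30, c(27, 25, 24), c(1, 1, 1),
                       c(-64, -37, -25))
  lr <- loss_rates_and_shares(s)
  expect_equal(lr$rate_Tg_per_yr, c(6.4, 3.7, 2.5))
  expect_equal(lr$mean_annual_rate_Tg_per_yr, 126 / 30)
  expect_equal(sum(lr$share_pct), 100)
  # equal decadal changes give equal shares
  eq <- printed_summary("Y", 5, 30, c(27, 25), c(1, 1), c(-10, -10))
  expect_equal(loss_rates_and_shares(eq)$share_pct, c(50, 50))
  zero <- printed_summary("Z", 5, 30, c(27, 25), c(1, 1), c(-5, 5))
  expect_error(loss_rates_and_shares(zero), "zero total change")
})
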