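test_that("step_day handles degenerate inputs and the stated worked example", {
  p <- soc_params()
  # empty system stays empty
  s0 <- step_day(pool_state(), p)
  expect_equal(total_soc(s0$state), 0)
  expect_equal(s0$flux$co2_C, 0)
  # frozen kinetics: f_env = 0 leaves the post-input state unchanged
  s1 <- step_day(pool_state(light = 5, heavy = 7), p, f_env = 0,
                 input_labile = 1)
  expect_equal(unclass(s1$state),
               c(labile = 1, resistant = 0, light = 5, heavy = 7))
  expect_equal(s1$flux$co2_C, 0)
  # light-only decomposition routes F_LH to heavy, remainder to CO2
  s2 <- step_day(pool_state(light = 100), p)
  d_lc <- 100 * (1 - exp(-2.5e-4))
  expect_equal(unname(s2$state["heavy"]), 0.3 * d_lc, tolerance = 1e-12)
  expect_equal(s2$flux$co2_C, 0.7 * d_lc, tolerance = 1e-12)
  expect_error(step_day(pool_state(light = 1), p, input_labile = -1),
               "non-negative")
  expect_error(step_day(pool_state(light = 1), p, f_env = -2), "non-negative")
})

test_that("single-step mass balance holds to relative 1e-12", {
  set.seed(11)
  for (i in 1:20) {
    p <- random_params()
    st <- pool_state(runif(1, 0, 50), runif(1, 0, 50), runif(1, 0, 50),
                     runif(1, 0, 50))
    f <- runif(1, 0, 3)
    bL <- runif(1, 0, 0.1); bR <- runif(1, 0, 0.1)
    out <- step_day(st, p, f, bL, bR)
    delta <- total_soc(out$state) - total_soc(st)
    expect_equal(delta, bL + bR - out$flux$co2_C,
                 tolerance = 1e-12 * max(1, total_soc(st)))
    expect_true(all(unclass(out$state) >= 0))
  }
})

test_that("run_trajectory matches the matrix-power closed form of the daily map", {
  set.seed(42)
  for (i in 1:5) {
    p <- random_params()
    x0 <- runif(4, 0, 40)
    bL <- runif(1, 0, 0.01); bR <- runif(1, 0, 0.01)
    n_days <- 10000L
    tr <- run_trajectory(pool_state(x0[1], x0[2], x0[3], x0[4]), p,
                         f_env = 1, input_labile = bL, input_resistant = bR,
                         n_days = n_days)
    oracle <- closed_form_state(x0, p, 1, bL, bR, n_days)
    expect_equal(unname(unclass(tr$final_state)), oracle, tolerance = 1e-8)
    # cumulative mass balance over the whole trajectory
    expect_equal(total_soc(tr$final_state) - sum(x0), tr$input_C - tr$co2_C,
                 tolerance = 1e-10 * max(1, sum(x0)))
  }
})

test_that("zero-day trajectories are identities and pure decay is monotone", {
  p <- soc_params()
  st <- pool_state(light = 10, heavy = 20)
  tr0 <- run_trajectory(st, p, n_days = 0)
  expect_equal(unclass(tr0$final_state), unclass(st))
  expect_length(tr0$soc_annual, 0)
  tr <- run_trajectory(st, p, f_env = 1, n_days = 10 * 365)
  expect_true(all(diff(c(total_soc(st), tr$soc_annual)) < 0))
})

test_that("an isolated pool halves over its nominal half-life", {
  p <- soc_params()
  for (pool in c("light", "heavy")) {
    K <- if (pool == "light") p$K_LC else p$K_HC
    n_days <- round(half_life_years(K) * 365.25)
    st <- do.call(pool_state, stats::setNames(list(100), pool))
    tr <- run_trajectory(st, p, f_env = 1, n_days = n_days)
    # the heavy pool only loses to CO2; light leaks F_LH of its flux to heavy,
    # so isolate by looking at the pool itself, not the total
    pool_final <- unclass(tr$final_state)[[pool]]
    expect_equal(pool_final / 100, exp(-K * n_days), tolerance = 1e-9)
    expect_equal(pool_final / 100, 0.5, tolerance = 1e-3)
  }
})

test_that("steady_state is a fixed point, linear in inputs, and guards f_env", {
  p <- soc_params()
  expect_equal(total_soc(steady_state(p, 1, 0, 0)), 0)
  ss <- steady_state(p, f_env = 0.8, input_labile = 0.003,
                     input_resistant = 0.002)
  after <- step_day(ss, p, f_env = 0.8, input_labile = 0.003,
                    input_resistant = 0.002)$state
  expect_equal(unclass(after), unclass(ss), tolerance = 1e-10)
  ss2 <- steady_state(p, f_env = 0.8, input_labile = 0.006,
                      input_resistant = 0.004)
  expect_equal(unclass(ss2), 2 * unclass(ss), tolerance = 1e-12)
  expect_error(steady_state(p, f_env = 0, input_labile = 0.01),
               "no steady state")
})

test_that("trajectories converge monotonically to the steady state", {
  p <- soc_params()
  bL <- 0.002; bR <- 0.0015
  ss <- unclass(steady_state(p, 1, bL, bR))
  st <- pool_state(light = 30, heavy = 10)
  dist <- numeric(40)
  for (y in 1:40) {
    tr <- run_trajectory(st, p, 1, bL, bR, n_days = 5 * 365)
    st <- tr$final_state
    dist[y] <- sqrt(sum((unclass(st) - ss)^2))
  }
  expect_true(all(diff(dist) < 0))
  expect_lt(dist[40] / dist[1], 0.2)
})

test_that("spin_up honours the initial split, rescale contract and slow-pool drift", {
  p <- soc_params()
  s0 <- spin_up(40, p, n_years = 0)
  expect_equal(unclass(s0),
               c(labile = 0, resistant = 0, light = 10, heavy = 30))
  for (ny in c(1, 25, 100)) {
    s <- spin_up(40, p, input_labile = 0.002, input_resistant = 0.001,
                 n_years = ny)
    expect_equal(total_soc(s), 40, tolerance = 1e-12)
  }
  # with zero input the faster light pool shrinks relative to heavy
  s_decay <- spin_up(40, p, n_years = 50)
  prop_light <- unclass(s_decay)[["light"]] / total_soc(s_decay)
  expect_lt(prop_light, 0.25)
  expect_error(spin_up(-5, p), "> 0")
  expect_error(spin_up(40, p, n_years = -1), ">= 0")
})

test_that("required_extra_input balances the carbon budget and is monotone in stock", {
  p <- soc_params()
  bL <- 0.002; bR <- 0.0015
  ss <- steady_state(p, 1, bL, bR)
  expect_equal(required_extra_input(ss, p, 1, bL, bR, horizon_years = 10), 0)
  st <- pool_state(light = 8, heavy = 24)
  need <- required_extra_input(st, p, 1, bL, bR, horizon_years = 20)
  expect_gt(need, 0)
  # adding the returned amount closes the SOC gap over the horizon
  per_day <- need / 365
  tr <- run_trajectory(st, p, 1, bL + 0.59 * per_day, bR + 0.41 * per_day,
                       n_days = 20 * 365)
  expect_lt(abs(total_soc(tr$final_state) - total_soc(st)), 0.05)
  # a larger stock decomposes faster, so needs more compensating input
  st_big <- pool_state(light = 10, heavy = 30)
  expect_gt(required_extra_input(st_big, p, 1, bL, bR, horizon_years = 20),
            need)
  expect_error(required_extra_input(st, p, 1, bL, bR, horizon_years = 0),
               ">= 1")
})

test_that("env_modifier is neutral by default and Q10-scaled in climate mode", {
  clim <- data.frame(tmax_C = c(25, 35), tmin_C = c(15, 25),
                     precip_mm = c(100, 100))
  expect_equal(env_modifier(clim, env_config()), c(1, 1))
  cfg <- env_config("climate", q10 = 2, t_ref = 20, precip_ref = 60,
                    precip_window = 30)
  f <- env_modifier(clim, cfg)
  # day 1: mean T 20 = reference, saturated moisture -> exactly 1
  expect_equal(f[1], 1)
  # day 2: +10 degC with Q10 = 2 doubles the rate
  expect_equal(f[2], 2)
  expect_true(all(env_modifier(
    data.frame(tmax_C = rnorm(50, 20, 10), tmin_C = rnorm(50, 10, 10),
               precip_mm = rexp(50, 1)), cfg) >= 0))
})
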