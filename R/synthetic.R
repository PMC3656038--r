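# Synthetic site trials and multi-region fixtures: daily climate with a
# seasonal cycle and Markov-chain rainfall, yield series that double over the
# simulation span, soil-property grids, and noisy depth-degraded SOC
# observations with known generating parameters.

#' Specification for the synthetic-data generators
#'
#' Defaults describe a southern-hemisphere wheat environment: mean annual
#' temperature 16.8-21.4 degC, annual precipitation 467-685 mm, yields
#' starting near 1 Mg ha^-1 in 1960 and doubling over 50 years with 20%
#' interannual variability, and regional initial SOC densities of roughly
#' 23-36 Mg C ha^-1 in the top 30 cm.
#'
#' @param n_years Simulation span in years (default 50).
#' @param start_year First simulated year (default 1960).
#' @param mat_range Range (degC) from which a region's mean annual
#'   temperature is drawn.
#' @param map_range Range (mm) from which a region's annual precipitation
#'   total is drawn.
#' @param temp_amplitude Seasonal temperature half-amplitude (degC).
#' @param temp_noise_sd Day-to-day temperature noise s.d. (degC).
#' @param rain_p_wd,rain_p_ww Markov-chain probabilities of a wet day after a
#'   dry day and after a wet day.
#' @param rain_shape Gamma shape for wet-day rainfall amounts.
#' @param yield_start Yield level in the first year (Mg ha^-1).
#' @param yield_doubling_years Years over which the yield trend doubles
#'   (default 50).
#' @param yield_cv Interannual yield coefficient of variation (default 0.2).
#' @param soc_obs_cv SOC observation noise coefficient of variation.
#' @param regions Data frame with columns `name`, `area_Mha`, `soc_lo`,
#'   `soc_hi` defining the synthetic region set (defaults emulate the five
#'   mainland wheat-belt states, areas summing to 15.08 Mha).
#' @param n_cells Soil grid cells per synthetic region (default 25).
#' @return A classed list of settings.
#' @export
synthetic_spec <- function(n_years = 50L, start_year = 1960L,
                           mat_range = c(16.8, 21.4),
                           map_range = c(467, 685),
                           temp_amplitude = 6, temp_noise_sd = 2,
                           rain_p_wd = 0.25, rain_p_ww = 0.55,
                           rain_shape = 0.8,
                           yield_start = 1.0, yield_doubling_years = 50L,
                           yield_cv = 0.2, soc_obs_cv = 0.05,
                           regions = NULL, n_cells = 25L) {
  if (is.null(regions)) {
    regions <- data.frame(
      name = c("QLD", "NSW", "WA", "SA", "VIC"),
      area_Mha = c(0.86, 3.83, 5.28, 2.87, 2.24),
      soc_lo = c(22, 21, 24, 23, 24),
      soc_hi = c(43, 42, 34, 34, 33),
      stringsAsFactors = FALSE)
  }
  n_years <- as.integer(n_years)
  if (n_years < 1L) stop("synthetic_spec: n_years must be >= 1", call. = FALSE)
  cvs <- c(yield_cv, soc_obs_cv)
  if (any(!is.finite(cvs)) || any(cvs < 0) || any(cvs >= 1))
    stop("synthetic_spec: CVs must lie in [0, 1)", call. = FALSE)
  structure(list(n_years = n_years, start_year = as.integer(start_year),
                 mat_range = mat_range, map_range = map_range,
                 temp_amplitude = temp_amplitude,
                 temp_noise_sd = temp_noise_sd,
                 rain_p_wd = rain_p_wd, rain_p_ww = rain_p_ww,
                 rain_shape = rain_shape,
                 yield_start = yield_start,
                 yield_doubling_years = as.integer(yield_doubling_years),
                 yield_cv = yield_cv, soc_obs_cv = soc_obs_cv,
                 regions = regions, n_cells = as.integer(n_cells)),
            class = "synthetic_spec")
}

#' Generate a daily climate series
#'
#' Temperature follows a sinusoidal seasonal cycle (warmest in January, as in
#' the southern hemisphere) plus Gaussian noise. Rainfall occurrence follows
#' a two-state Markov chain and wet-day amounts a gamma distribution whose
#' mean is chosen so the expected annual total matches `map`. Radiation,
#' relative humidity and wind are plausible filler series in the same
#' layout as a SILO-style record.
#'
#' @param spec A [synthetic_spec()].
#' @param mat Target mean annual temperature (degC; default the midpoint of
#'   `spec$mat_range`).
#' @param map Target annual precipitation (mm; default the midpoint of
#'   `spec$map_range`).
#' @param n_years Number of years (default `spec$n_years`).
#' @param seed Optional integer seed (set before generation).
#' @return Data frame with one row per day (365-day years) and columns
#'   `year`, `doy`, `tmax_C`, `tmin_C`, `precip_mm`, `radiation_MJ_m2`,
#'   `rh_pct`, `wind_m_s`.
#' @export
gen_climate <- function(spec = synthetic_spec(), mat = mean(spec$mat_range),
                        map = mean(spec$map_range),
                        n_years = spec$n_years, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_days <- as.integer(n_years) * 365L
  doy <- rep(1:365, n_years)
  season <- cos(2 * pi * (doy - 15) / 365)  # peak mid-January
  tmean <- mat + spec$temp_amplitude * season +
    stats::rnorm(n_days, 0, spec$temp_noise_sd)
  # stationary wet-day probability of the occurrence chain
  p_wet <- spec$rain_p_wd / (1 + spec$rain_p_wd - spec$rain_p_ww)
  wet <- logical(n_days)
  u <- stats::runif(n_days)
  prev <- u[1L] < p_wet
  wet[1L] <- prev
  for (t in 2:n_days) {
    p <- if (prev) spec$rain_p_ww else spec$rain_p_wd
    prev <- u[t] < p
    wet[t] <- prev
  }
  mean_amount <- map / (365 * p_wet)
  precip <- numeric(n_days)
  nw <- sum(wet)
  if (nw > 0L && map > 0)
    precip[wet] <- stats::rgamma(nw, shape = spec$rain_shape,
                                 scale = mean_amount / spec$rain_shape)
  data.frame(
    year = rep(seq_len(n_years), each = 365L),
    doy = doy,
    tmax_C = tmean + 5,
    tmin_C = tmean - 5,
    precip_mm = precip,
    radiation_MJ_m2 = pmax(2, 18 + 8 * season + stats::rnorm(n_days, 0, 2)),
    rh_pct = pmin(100, pmax(10, 55 - 10 * season + stats::rnorm(n_days, 0, 8))),
    wind_m_s = pmax(0, 3 + stats::rnorm(n_days, 0, 1))
  )
}

#' Generate an annual yield series with a doubling trend
#'
#' The trend rises linearly from `yield_start` to twice that level across
#' `yield_doubling_years`; interannual variability is multiplicative
#' lognormal noise with the stated coefficient of variation, mean-corrected
#' so the expectation of each year equals its trend value.
#'
#' @param spec A [synthetic_spec()].
#' @param n_years Number of years (default `spec$n_years`).
#' @param seed Optional integer seed.
#' @return Numeric vector of non-negative annual yields (Mg ha^-1).
#' @export
gen_yields <- function(spec = synthetic_spec(), n_years = spec$n_years,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  span <- max(1L, spec$yield_doubling_years - 1L)
  trend <- spec$yield_start * (1 + (seq_len(n_years) - 1) / span)
  if (spec$yield_cv == 0) return(trend)
  sdlog <- sqrt(log(1 + spec$yield_cv^2))
  trend * stats::rlnorm(n_years, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic site trial with known truth
#'
#' Simulates the true SOC trajectory with the four-pool model from an
#' initial light/heavy split, converts synthetic yields to daily carbon
#' inputs, and emits sparse noisy SOC observations, some degraded to
#' 0-10 cm or 0-20 cm depths by dividing the 0-30 cm truth by the depth
#' coefficients (so depth conversion is exactly invertible at zero noise).
#' The generating parameters ride along for recovery tests.
#'
#' @param spec A [synthetic_spec()].
#' @param params The generating [soc_params()].
#' @param initial_soc Initial SOC density (Mg C ha^-1, default 30).
#' @param retention Stubble retention fraction (default 0.95).
#' @param cinput A [c_input_config()].
#' @param obs_every Observation interval in years (default 5).
#' @param f_env Constant environmental modifier for the site (default 1;
#'   lower values emulate drier/cooler sites).
#' @param seed Optional integer seed.
#' @return A [site_trial()] whose `observations` carry cycling depths
#'   `0-30`, `0-10`, `0-20` and whose `true_params` is `params`.
#' @export
gen_site_trial <- function(spec = synthetic_spec(), params = soc_params(),
                           initial_soc = 30, retention = 0.95,
                           cinput = c_input_config(), obs_every = 5L,
                           f_env = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  yields <- gen_yields(spec)
  annual <- annual_c_input(yields, cinput, retention)
  daily <- daily_input_series(annual, cinput)
  state0 <- pool_state(light = 0.25 * initial_soc, heavy = 0.75 * initial_soc)
  obs_years <- seq(obs_every, spec$n_years, by = obs_every)
  obs_days <- obs_years * 365L
  traj <- run_trajectory(state0, params, f_env = f_env,
                         input_labile = daily$labile,
                         input_resistant = daily$resistant,
                         n_days = spec$n_years * 365L,
                         record_days = obs_days)
  truth30 <- traj$soc_days
  depths <- rep(c("0-30", "0-10", "0-20"), length.out = length(obs_days))
  coef <- unname(DEPTH_COEF[depths])
  noise <- if (spec$soc_obs_cv > 0)
    stats::rnorm(length(obs_days), 1, spec$soc_obs_cv) else rep(1, length(obs_days))
  obs <- data.frame(day = obs_days,
                    value = pmax(0, truth30 / coef * noise),
                    depth = depths, stringsAsFactors = FALSE)
  site_trial(initial_state = state0, f_env = f_env,
             input_labile = daily$labile, input_resistant = daily$resistant,
             observations = obs, true_params = params)
}

#' Generate a synthetic five-region fixture set
#'
#' Builds one [region_inputs()] per configured region: the printed-area
#' defaults (summing to 15.08 Mha), a soil grid with initial SOC drawn
#' uniformly inside each region's density range plus plausible covariates,
#' a yield series and a daily climate series, with retention from
#' [default_retention_table()].
#'
#' @param spec A [synthetic_spec()].
#' @param seed Optional integer seed (the whole set is a pure function of
#'   `(spec, seed)`).
#' @param with_climate Generate the daily climate series (default `TRUE`;
#'   skipping it is faster when decomposition is neutral).
#' @return Named list of [region_inputs()].
#' @export
gen_region_set <- function(spec = synthetic_spec(), seed = NULL,
                           with_climate = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  regions <- spec$regions
  out <- vector("list", nrow(regions))
  names(out) <- regions$name
  for (i in seq_len(nrow(regions))) {
    soc <- stats::runif(spec$n_cells, regions$soc_lo[i], regions$soc_hi[i])
    soil <- data.frame(
      cell_id = seq_len(spec$n_cells),
      soc_Mg_ha = soc,
      total_n_g_kg = soc / 30,  # C:N near 10 at typical bulk density
      clay_frac = stats::runif(spec$n_cells, 0.10, 0.45),
      sand_frac = stats::runif(spec$n_cells, 0.30, 0.75),
      ph = stats::runif(spec$n_cells, 5.5, 8.5),
      bulk_density_g_cm3 = stats::runif(spec$n_cells, 1.1, 1.6)
    )
    soil$sand_frac <- pmin(soil$sand_frac, 0.98 - soil$clay_frac)
    yields <- data.frame(
      year = spec$start_year + seq_len(spec$n_years) - 1L,
      yield_Mg_per_ha = gen_yields(spec))
    climate <- if (with_climate)
      gen_climate(spec,
                  mat = stats::runif(1, spec$mat_range[1], spec$mat_range[2]),
                  map = stats::runif(1, spec$map_range[1], spec$map_range[2]))
      else NULL
    out[[i]] <- region_inputs(name = regions$name[i],
                              area_Mha = regions$area_Mha[i],
                              soil = soil, yields = yields,
                              retention = retention_for_region(regions$name[i]),
                              climate = climate)
  }
  out
}
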