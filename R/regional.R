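# Regional upscaling: input distributions, Monte Carlo ensembles, decadal
# accounting and belt-level aggregation. Unit identity used throughout:
# 1 Mg ha^-1 over 1 Mha = 1 Tg.

#' Regional model inputs
#'
#' One natural-resource-management (NRM) region: its cropped area, a sample
#' of topsoil property grid cells, the annual yield series, the stubble
#' retention fraction and (optionally) a daily climate series.
#'
#' @param name Region name (e.g. `"QLD"`).
#' @param area_Mha Cropped area (million hectares, > 0).
#' @param soil Data frame of grid cells with at least a `soc_Mg_ha` column
#'   (topsoil SOC density); other property columns (total N, clay, sand, pH,
#'   bulk density) are carried along.
#' @param yields Data frame with columns `year` and `yield_Mg_per_ha`
#'   covering the simulation span in consecutive years.
#' @param retention Retained fraction of above-ground residue (in `[0, 1]`).
#' @param climate Optional daily climate data frame (see [gen_climate()] for
#'   the column layout); required only for climate-driven decomposition.
#' @return A classed list.
#' @export
region_inputs <- function(name, area_Mha, soil, yields, retention,
                          climate = NULL) {
  if (!is.finite(area_Mha) || area_Mha <= 0)
    stop("region_inputs: area_Mha must be > 0", call. = FALSE)
  if (!is.data.frame(soil) || nrow(soil) == 0L || !"soc_Mg_ha" %in% names(soil))
    stop("region_inputs: soil must be a non-empty data frame with soc_Mg_ha",
         call. = FALSE)
  need <- c("year", "yield_Mg_per_ha")
  if (!is.data.frame(yields) || !all(need %in% names(yields)) ||
      nrow(yields) == 0L)
    stop("region_inputs: yields needs columns year and yield_Mg_per_ha",
         call. = FALSE)
  if (any(diff(yields$year) != 1L))
    stop("region_inputs: yield years must be consecutive", call. = FALSE)
  if (!is.finite(retention) || retention < 0 || retention > 1)
    stop("region_inputs: retention must lie in [0, 1]", call. = FALSE)
  structure(list(name = name, area_Mha = area_Mha, soil = soil,
                 yields = yields, retention = retention, climate = climate),
            class = "region_inputs")
}

#' Monte Carlo configuration
#'
#' @param n_runs Ensemble size (default 300).
#' @param input_halfwidth Relative half-width of the uniform carbon-input
#'   multiplier (default 0.10, i.e. mean +/- 10%).
#' @param ci_level Confidence level for the empirical intervals (default
#'   0.95).
#' @param seed Optional integer seed set before the ensemble draws, making
#'   the result reproducible.
#' @return A classed list.
#' @export
mc_config <- function(n_runs = 300L, input_halfwidth = 0.10,
                      ci_level = 0.95, seed = NULL) {
  n_runs <- as.integer(n_runs)
  if (is.na(n_runs) || n_runs < 1L)
    stop("mc_config: n_runs must be >= 1", call. = FALSE)
  if (!is.finite(input_halfwidth) || input_halfwidth < 0 || input_halfwidth >= 1)
    stop("mc_config: input_halfwidth must lie in [0, 1)", call. = FALSE)
  if (!is.finite(ci_level) || ci_level <= 0 || ci_level >= 1)
    stop("mc_config: ci_level must lie in (0, 1)", call. = FALSE)
  structure(list(n_runs = n_runs, input_halfwidth = input_halfwidth,
                 ci_level = ci_level, seed = seed), class = "mc_config")
}

#' Draw initial soil states from the empirical grid distribution
#'
#' Samples grid cells uniformly with replacement: the empirical probability
#' distribution of the region's topsoil properties.
#'
#' @param soil Non-empty data frame of grid cells.
#' @param n Number of draws (default 1).
#' @return Data frame of `n` sampled rows.
#' @export
sample_soil_state <- function(soil, n = 1L) {
  if (!is.data.frame(soil) || nrow(soil) == 0L)
    stop("sample_soil_state: soil sample is empty", call. = FALSE)
  soil[sample.int(nrow(soil), n, replace = TRUE), , drop = FALSE]
}

#' Draw carbon-input scale multipliers
#'
#' Uniform draws on `[1 - halfwidth, 1 + halfwidth]`.
#'
#' @param n Number of draws.
#' @param halfwidth Relative half-width (in `[0, 1)`).
#' @return Numeric vector of multipliers.
#' @export
sample_input_scale <- function(n, halfwidth = 0.10) {
  if (!is.finite(halfwidth) || halfwidth < 0 || halfwidth >= 1)
    stop("sample_input_scale: halfwidth must lie in [0, 1)", call. = FALSE)
  if (halfwidth == 0) return(rep(1, n))
  stats::runif(n, 1 - halfwidth, 1 + halfwidth)
}

# Shared preparation for regional runs: annual C input, daily forcing, and
# the daily environmental modifier series.
prepare_region_forcing <- function(region, cinput, env, days_per_year) {
  annual_input <- annual_c_input(region$yields$yield_Mg_per_ha, cinput,
                                 region$retention)
  daily <- daily_input_series(annual_input, cinput,
                              days_per_year = days_per_year)
  n_days <- length(daily$labile)
  if (env$mode == "neutral") {
    f_env <- 1
  } else {
    if (is.null(region$climate))
      stop("run_region: climate-driven mode needs a climate series", call. = FALSE)
    f_env <- env_modifier(region$climate, env)
    if (length(f_env) < n_days)
      stop("run_region: climate series shorter than the simulation", call. = FALSE)
    f_env <- f_env[seq_len(n_days)]
  }
  list(annual_input = annual_input, daily = daily, f_env = f_env,
       n_days = n_days)
}

#' Deterministic regional simulation
#'
#' Runs the model for one region at the grid-mean initial SOC with unscaled
#' carbon inputs: spin-up (recycling the region's forcing) followed by the
#' daily simulation over the yield years. Deterministic given its inputs.
#'
#' @param region A [region_inputs()].
#' @param params A [soc_params()].
#' @param cinput A [c_input_config()].
#' @param env An [env_config()].
#' @param spin_up_years Spin-up length in years (default 100).
#' @param days_per_year Days per simulated year (default 365).
#' @return List with `years` (start-of-year labels, length n+1), `soc`
#'   (start-of-year SOC densities, Mg C ha^-1, length n+1; the first value is
#'   the post-spin-up initial density), `c_input` (annual inputs, length n)
#'   and `final_state`.
#' @export
run_region <- function(region, params = soc_params(),
                       cinput = c_input_config(), env = env_config(),
                       spin_up_years = 100L, days_per_year = 365L) {
  fz <- prepare_region_forcing(region, cinput, env, days_per_year)
  soc0 <- mean(region$soil$soc_Mg_ha)
  state0 <- spin_up(soc0, params, fz$f_env, fz$daily$labile,
                    fz$daily$resistant, n_years = spin_up_years,
                    days_per_year = days_per_year)
  sim <- sim_pools(state0, params, fz$f_env, fz$daily$labile,
                   fz$daily$resistant, n_days = fz$n_days,
                   days_per_year = days_per_year)
  n_years <- nrow(region$yields)
  fs <- sim$final[1L, ]
  list(years = c(region$yields$year, region$yields$year[n_years] + 1L),
       soc = c(soc0, as.numeric(sim$soc_annual[1L, ])),
       c_input = fz$annual_input,
       final_state = pool_state(fs[["labile"]], fs[["resistant"]],
                                fs[["light"]], fs[["heavy"]]))
}

#' Monte Carlo ensemble for one region
#'
#' Draws `n_runs` initial soil states from the empirical grid distribution
#' and carbon-input multipliers from the uniform `mean +/- halfwidth`
#' distribution, then runs spin-up and simulation for every ensemble member.
#' Empirical confidence bounds are the `(1 - ci_level)/2` and
#' `1 - (1 - ci_level)/2` percentiles across runs. With a fixed `seed` in
#' `cfg`, results are exactly reproducible.
#'
#' @param region A [region_inputs()].
#' @param params A [soc_params()].
#' @param cfg An [mc_config()].
#' @param cinput A [c_input_config()].
#' @param env An [env_config()].
#' @param spin_up_years Spin-up length in years (default 100).
#' @param days_per_year Days per simulated year (default 365).
#' @return List with `years`, matrices `soc` and `c_input` (one row per
#'   run), summary series `mean`, `lo`, `hi` (SOC density), the draw vectors
#'   `scale` and `cells`, and the configuration used.
#' @export
monte_carlo_region <- function(region, params = soc_params(),
                               cfg = mc_config(), cinput = c_input_config(),
                               env = env_config(), spin_up_years = 100L,
                               days_per_year = 365L) {
  if (!inherits(cfg, "mc_config")) stop("cfg must be an mc_config", call. = FALSE)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_runs
  fz <- prepare_region_forcing(region, cinput, env, days_per_year)
  cells <- sample.int(nrow(region$soil), n, replace = TRUE)
  soc0 <- region$soil$soc_Mg_ha[cells]
  scale <- sample_input_scale(n, cfg$input_halfwidth)

  # spin-up, vectorized across the ensemble
  state <- cbind(labile = numeric(n), resistant = numeric(n),
                 light = 0.25 * soc0, heavy = 0.75 * soc0)
  if (spin_up_years > 0L) {
    nd_spin <- as.integer(spin_up_years) * as.integer(days_per_year)
    spin <- sim_pools(state, params,
                      f_env = rep_len(fz$f_env, nd_spin),
                      input_labile = rep_len(fz$daily$labile, nd_spin),
                      input_resistant = rep_len(fz$daily$resistant, nd_spin),
                      n_days = nd_spin, scale = scale,
                      days_per_year = days_per_year)
    state <- spin$final * (soc0 / rowSums(spin$final))
  }

  sim <- sim_pools(state, params, fz$f_env, fz$daily$labile,
                   fz$daily$resistant, n_days = fz$n_days, scale = scale,
                   days_per_year = days_per_year)
  soc <- cbind(soc0, sim$soc_annual, deparse.level = 0)
  alpha <- (1 - cfg$ci_level) / 2
  n_years <- nrow(region$yields)
  list(years = c(region$yields$year, region$yields$year[n_years] + 1L),
       soc = soc,
       c_input = outer(scale, fz$annual_input),
       mean = colMeans(soc),
       lo = apply(soc, 2L, stats::quantile, probs = alpha, names = FALSE),
       hi = apply(soc, 2L, stats::quantile, probs = 1 - alpha, names = FALSE),
       scale = scale, cells = cells, cfg = cfg, region = region$name,
       area_Mha = region$area_Mha)
}

decade_indices <- function(n_years) {
  if (n_years %% 10L != 0L)
    stop("series must span whole decades", call. = FALSE)
  split(seq_len(n_years), rep(seq_len(n_years %/% 10L), each = 10L))
}

#' Decadal accounting for one annual SOC series
#'
#' Splits a start-of-year SOC density series into decades and computes the
#' decade mean density, mean carbon input, and stock change
#' `(density at decade end - density at decade start) * area` in Tg. Decadal
#' changes telescope exactly to the whole-period total.
#'
#' @param soc Start-of-year SOC densities (Mg C ha^-1), length
#'   `n_years + 1` where `n_years` is a multiple of 10.
#' @param years Start-of-year labels, length `n_years + 1`.
#' @param c_input Annual carbon inputs (Mg C ha^-1 yr^-1), length `n_years`.
#' @param area_Mha Region area (Mha).
#' @param name Region name for the summary.
#' @return A `regional_summary`: list with `region`, `area_Mha`,
#'   `initial_density`, a `decades` data frame (`decade`, `density`,
#'   `input`, `change_Tg`) and `total_change_Tg`.
#' @export
decadal_summary <- function(soc, years, c_input, area_Mha, name = "region") {
  n_years <- length(soc) - 1L
  if (length(years) != n_years + 1L || length(c_input) != n_years)
    stop("decadal_summary: series lengths inconsistent", call. = FALSE)
  idx <- decade_indices(n_years)
  decades <- vapply(idx, function(i) paste0(years[i[1L]], "s"), character(1))
  density <- vapply(idx, function(i) mean(soc[i]), numeric(1))
  input <- vapply(idx, function(i) mean(c_input[i]), numeric(1))
  change <- vapply(idx, function(i) (soc[i[10L] + 1L] - soc[i[1L]]) * area_Mha,
                   numeric(1))
  structure(list(region = name, area_Mha = area_Mha,
                 initial_density = soc[1L],
                 decades = data.frame(decade = unname(decades),
                                      density = unname(density),
                                      input = unname(input),
                                      change_Tg = unname(change),
                                      stringsAsFactors = FALSE),
                 total_change_Tg = sum(change)),
            class = "regional_summary")
}

#' Decadal summary of a Monte Carlo ensemble
#'
#' Applies the decadal accounting of [decadal_summary()] to every ensemble
#' member and attaches empirical confidence bounds (percentiles across runs)
#' for the decade densities, stock changes, the initial density and the
#' total change.
#'
#' @param mc Result of [monte_carlo_region()].
#' @return A `regional_summary` whose `decades` frame additionally has
#'   `density_lo`, `density_hi`, `change_lo`, `change_hi` columns, plus
#'   `initial_lo/hi` and `total_lo/hi` fields.
#' @export
mc_decadal_summary <- function(mc) {
  n_years <- ncol(mc$soc) - 1L
  idx <- decade_indices(n_years)
  alpha <- (1 - mc$cfg$ci_level) / 2
  q <- function(x, p) stats::quantile(x, probs = p, names = FALSE)
  dens_runs <- sapply(idx, function(i) rowMeans(mc$soc[, i, drop = FALSE]))
  chg_runs <- sapply(idx, function(i)
    (mc$soc[, i[10L] + 1L] - mc$soc[, i[1L]]) * mc$area_Mha)
  if (is.null(dim(dens_runs))) {  # single-run ensemble
    dens_runs <- matrix(dens_runs, nrow = 1L)
    chg_runs <- matrix(chg_runs, nrow = 1L)
  }
  inp_runs <- sapply(idx, function(i) rowMeans(mc$c_input[, i, drop = FALSE]))
  if (is.null(dim(inp_runs))) inp_runs <- matrix(inp_runs, nrow = 1L)
  total_runs <- rowSums(chg_runs)
  out <- decadal_summary(mc$mean, mc$years, colMeans(mc$c_input),
                         mc$area_Mha, name = mc$region)
  out$decades$density <- colMeans(dens_runs)
  out$decades$input <- colMeans(inp_runs)
  out$decades$change_Tg <- colMeans(chg_runs)
  out$decades$density_lo <- apply(dens_runs, 2L, q, alpha)
  out$decades$density_hi <- apply(dens_runs, 2L, q, 1 - alpha)
  out$decades$change_lo <- apply(chg_runs, 2L, q, alpha)
  out$decades$change_hi <- apply(chg_runs, 2L, q, 1 - alpha)
  out$initial_density <- mean(mc$soc[, 1L])
  out$initial_lo <- q(mc$soc[, 1L], alpha)
  out$initial_hi <- q(mc$soc[, 1L], 1 - alpha)
  out$total_change_Tg <- mean(total_runs)
  out$total_lo <- q(total_runs, alpha)
  out$total_hi <- q(total_runs, 1 - alpha)
  out
}

#' Aggregate regional summaries to the whole belt
#'
#' Areas and stock changes (including confidence bounds) sum across regions;
#' densities and carbon inputs are area-weighted means. Region names must be
#' unique.
#'
#' @param summaries Non-empty list of `regional_summary` objects.
#' @param name Name for the aggregate (default `"Wheat belt"`).
#' @return A belt-level `regional_summary`.
#' @export
aggregate_belt <- function(summaries, name = "Wheat belt") {
  if (!is.list(summaries) || length(summaries) == 0L)
    stop("aggregate_belt: need at least one summary", call. = FALSE)
  nms <- vapply(summaries, function(s) s$region, character(1))
  if (anyDuplicated(nms))
    stop("aggregate_belt: duplicate region names", call. = FALSE)
  areas <- vapply(summaries, function(s) s$area_Mha, numeric(1))
  area_tot <- sum(areas)
  w <- areas / area_tot
  wmean_col <- function(col)
    Reduce(`+`, Map(function(s, wi) wi * s$decades[[col]], summaries, w))
  sum_col <- function(col)
    Reduce(`+`, lapply(summaries, function(s) s$decades[[col]]))
  dec <- summaries[[1L]]$decades["decade"]
  dec$density <- wmean_col("density")
  dec$input <- wmean_col("input")
  dec$change_Tg <- sum_col("change_Tg")
  has_ci <- all(vapply(summaries,
                       function(s) "change_lo" %in% names(s$decades),
                       logical(1)))
  if (has_ci) {
    dec$density_lo <- wmean_col("density_lo")
    dec$density_hi <- wmean_col("density_hi")
    dec$change_lo <- sum_col("change_lo")
    dec$change_hi <- sum_col("change_hi")
  }
  out <- structure(list(region = name, area_Mha = area_tot,
                        initial_density = sum(w * vapply(summaries,
                          function(s) s$initial_density, numeric(1))),
                        decades = dec,
                        total_change_Tg = sum(vapply(summaries,
                          function(s) s$total_change_Tg, numeric(1)))),
                   class = "regional_summary")
  if (has_ci) {
    out$initial_lo <- sum(w * vapply(summaries, function(s) s$initial_lo, numeric(1)))
    out$initial_hi <- sum(w * vapply(summaries, function(s) s$initial_hi, numeric(1)))
    out$total_lo <- sum(vapply(summaries, function(s) s$total_lo, numeric(1)))
    out$total_hi <- sum(vapply(summaries, function(s) s$total_hi, numeric(1)))
  }
  out
}

#' Decadal loss rates and period shares
#'
#' Converts decadal stock changes into mean annual rates (`|change| / 10`
#' Tg yr^-1 per decade; `|total| / (10 * n_decades)` for the whole period)
#' and each decade's percentage share of the total change.
#'
#' @param summary A `regional_summary`.
#' @return List with `decade`, `rate_Tg_per_yr` (per decade),
#'   `share_pct` (per decade, summing to 100) and
#'   `mean_annual_rate_Tg_per_yr`.
#' @export
loss_rates_and_shares <- function(summary) {
  changes <- summary$decades$change_Tg
  total <- sum(changes)
  if (total == 0)
    stop("loss_rates_and_shares: zero total change, shares undefined",
         call. = FALSE)
  list(decade = summary$decades$decade,
       rate_Tg_per_yr = abs(changes) / 10,
       share_pct = 100 * changes / total,
       mean_annual_rate_Tg_per_yr = abs(total) / (10 * length(changes)))
}

#' @export
print.regional_summary <- function(x, ...) {
  cat("<regional_summary>", x$region, "-", format(x$area_Mha), "Mha\n")
  cat("initial SOC density:", format(x$initial_density, digits = 4),
      "Mg C ha^-1\n")
  print(x$decades, row.names = FALSE, digits = 4)
  cat("total change:", format(x$total_change_Tg, digits = 4), "Tg C\n")
  invisible(x)
}
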