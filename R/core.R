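# Core model operations: single-day step, trajectories, spin-up,
# steady states and the required-extra-input calculation.

#' Advance the four-pool model by one day
#'
#' The day's fresh-residue carbon is added to the labile and resistant pools
#' first; each pool `i` then decomposes by `D_i = C_i * (1 - exp(-K_i *
#' f_env))`; the light pool gains `F_LL * D_L + F_RL * D_R`, the heavy pool
#' gains `F_LH * D_LC`, and the remainder of every decomposition flux leaves
#' as CO2 (the heavy pool decomposes to CO2 only). Mass balance
#' `delta(total) = input - CO2` holds to machine precision.
#'
#' @param state A [pool_state()].
#' @param params A [soc_params()].
#' @param f_env Environmental rate modifier for the day (>= 0; 1 = reference
#'   conditions).
#' @param input_labile,input_resistant Fresh carbon added to the labile and
#'   resistant pools (Mg C ha^-1 d^-1, >= 0).
#' @return A list with elements `state` (the new [pool_state()]) and `flux`
#'   (list with `input_C` and `co2_C`, both Mg C ha^-1 d^-1).
#' @export
#' @examples
#' p <- soc_params()
#' step_day(pool_state(light = 100), p)$flux$co2_C
step_day <- function(state, params, f_env = 1,
                     input_labile = 0, input_resistant = 0) {
  x <- unclass(state)
  if (any(is.na(x))) stop("step_day: NaN in state", call. = FALSE)
  if (!is.finite(f_env) || f_env < 0)
    stop("step_day: f_env must be a non-negative number", call. = FALSE)
  if (input_labile < 0 || input_resistant < 0)
    stop("step_day: carbon inputs must be non-negative", call. = FALSE)
  L <- x[[1L]] + input_labile
  Rr <- x[[2L]] + input_resistant
  LC <- x[[3L]]
  HC <- x[[4L]]
  D_L <- L * -expm1(-params$K_L * f_env)
  D_R <- Rr * -expm1(-params$K_R * f_env)
  D_LC <- LC * -expm1(-params$K_LC * f_env)
  D_HC <- HC * -expm1(-params$K_HC * f_env)
  new_state <- pool_state(
    labile = L - D_L,
    resistant = Rr - D_R,
    light = LC - D_LC + params$F_LL * D_L + params$F_RL * D_R,
    heavy = HC - D_HC + params$F_LH * D_LC
  )
  co2 <- (1 - params$F_LL) * D_L + (1 - params$F_RL) * D_R +
    (1 - params$F_LH) * D_LC + D_HC
  list(state = new_state,
       flux = list(input_C = input_labile + input_resistant, co2_C = co2))
}

#' Run a multi-day trajectory of the four-pool model
#'
#' Applies the daily operator of [step_day()] over `n_days`, returning SOC
#' density sampled at the end of each simulated year together with annual CO2
#' efflux and the final state. Cumulative mass balance (total input minus
#' total CO2 equals the SOC change) holds to near machine precision.
#'
#' @param initial A [pool_state()] at day 0.
#' @param params A [soc_params()].
#' @param f_env Environmental modifier: scalar or daily series of length
#'   >= `n_days`.
#' @param input_labile,input_resistant Daily carbon inputs (Mg C ha^-1 d^-1):
#'   scalars or series of length >= `n_days`.
#' @param n_days Number of days to simulate (>= 0).
#' @param days_per_year Days per simulated year used for annual sampling
#'   (default 365).
#' @param record_days Optional day indices at which to record SOC density.
#' @return List with `soc_annual`, `co2_annual` (numeric vectors, one value
#'   per complete simulated year), `final_state` (a [pool_state()]),
#'   `soc_days` (SOC at `record_days`), and cumulative `input_C` and `co2_C`.
#' @export
run_trajectory <- function(initial, params, f_env = 1,
                           input_labile = 0, input_resistant = 0,
                           n_days, days_per_year = 365L,
                           record_days = NULL) {
  sim <- sim_pools(initial, params, f_env, input_labile, input_resistant,
                   n_days = n_days, days_per_year = days_per_year,
                   record_days = if (is.null(record_days)) integer(0) else record_days)
  fs <- sim$final[1L, ]
  list(soc_annual = as.numeric(sim$soc_annual[1L, ]),
       co2_annual = as.numeric(sim$co2_annual[1L, ]),
       final_state = pool_state(fs[["labile"]], fs[["resistant"]],
                                fs[["light"]], fs[["heavy"]]),
       soc_days = as.numeric(sim$soc_days[1L, ]),
       input_C = sim$input_total[1L],
       co2_C = sim$co2_total[1L])
}

#' Spin-up initialisation of the pool distribution
#'
#' Starts from an assumed light/heavy split of the observed total SOC (0.25 /
#' 0.75 by default, labile and resistant empty), runs the model for
#' `n_years` under the supplied forcing (series shorter than the spin-up are
#' recycled), and finally rescales all pools by a common factor so the total
#' equals the observed starting SOC while keeping the spun-up proportions.
#'
#' @param total_soc_start Observed initial SOC density (Mg C ha^-1, > 0).
#' @param params A [soc_params()].
#' @param f_env,input_labile,input_resistant Daily forcing (scalars or
#'   series; recycled cyclically over the spin-up).
#' @param n_years Spin-up length in years (>= 0, default 100).
#' @param days_per_year Days per simulated year (default 365).
#' @param light_fraction Initial light-C fraction of the total (default
#'   0.25; the heavy fraction is the complement).
#' @return A [pool_state()] with total equal to `total_soc_start`.
#' @export
spin_up <- function(total_soc_start, params, f_env = 1,
                    input_labile = 0, input_resistant = 0,
                    n_years = 100L, days_per_year = 365L,
                    light_fraction = 0.25) {
  if (!is.finite(total_soc_start) || total_soc_start <= 0)
    stop("spin_up: total_soc_start must be > 0", call. = FALSE)
  n_years <- as.integer(n_years)
  if (n_years < 0L) stop("spin_up: n_years must be >= 0", call. = FALSE)
  state <- pool_state(light = light_fraction * total_soc_start,
                      heavy = (1 - light_fraction) * total_soc_start)
  if (n_years == 0L) return(state)
  n_days <- n_years * as.integer(days_per_year)
  sim <- sim_pools(state, params,
                   f_env = rep_len(f_env, n_days),
                   input_labile = rep_len(input_labile, n_days),
                   input_resistant = rep_len(input_resistant, n_days),
                   n_days = n_days, days_per_year = days_per_year)
  fs <- sim$final[1L, ]
  fac <- total_soc_start / sum(fs)
  pool_state(fs[["labile"]] * fac, fs[["resistant"]] * fac,
             fs[["light"]] * fac, fs[["heavy"]] * fac)
}

#' Steady state of the daily map under constant forcing
#'
#' Closed-form fixed point of the daily operator with a constant
#' environmental modifier and constant daily inputs. At the fixed point every
#' pool's daily decomposition equals its daily supply, so applying
#' [step_day()] leaves the state unchanged. The map is linear in the inputs:
#' doubling both inputs doubles every steady-state pool.
#'
#' @param params A [soc_params()].
#' @param f_env Constant environmental modifier (> 0 when any input is
#'   positive).
#' @param input_labile,input_resistant Constant daily inputs
#'   (Mg C ha^-1 d^-1, >= 0).
#' @return The fixed-point [pool_state()].
#' @export
steady_state <- function(params, f_env = 1, input_labile = 0,
                         input_resistant = 0) {
  if (input_labile < 0 || input_resistant < 0)
    stop("steady_state: inputs must be >= 0", call. = FALSE)
  if (f_env <= 0) {
    if (input_labile > 0 || input_resistant > 0)
      stop("steady_state: no steady state with f_env <= 0 and positive input",
           call. = FALSE)
    return(pool_state())
  }
  if (input_labile == 0 && input_resistant == 0) return(pool_state())
  a <- function(K) exp(-K * f_env)
  d <- function(K) -expm1(-K * f_env)
  # at the fixed point, decomposition of labile/resistant equals their input
  L <- input_labile * a(params$K_L) / d(params$K_L)
  Rr <- input_resistant * a(params$K_R) / d(params$K_R)
  gain_light <- params$F_LL * input_labile + params$F_RL * input_resistant
  LC <- gain_light / d(params$K_LC)
  HC <- params$F_LH * gain_light / d(params$K_HC)
  pool_state(L, Rr, LC, HC)
}

#' Minimum additional carbon input needed to halt SOC decline
#'
#' Finds, by bisection (to `tol` Mg C ha^-1 yr^-1), the smallest additional
#' annual carbon input - spread uniformly over the year on top of the
#' baseline forcing - such that SOC at the end of the horizon is at least the
#' starting SOC. Returns 0 when the baseline trajectory is already
#' non-decreasing over the horizon.
#'
#' @param state Starting [pool_state()].
#' @param params A [soc_params()].
#' @param f_env,input_labile,input_resistant Baseline daily forcing
#'   (recycled cyclically over the horizon).
#' @param horizon_years Evaluation horizon in years (>= 1).
#' @param split_labile Fraction of the extra input entering the labile pool
#'   (remainder to resistant); default 0.59 as for fresh residue.
#' @param tol Bisection tolerance (Mg C ha^-1 yr^-1, default 1e-3).
#' @param days_per_year Days per simulated year (default 365).
#' @return Additional annual input (Mg C ha^-1 yr^-1, >= 0).
#' @export
required_extra_input <- function(state, params, f_env = 1,
                                 input_labile = 0, input_resistant = 0,
                                 horizon_years, split_labile = 0.59,
                                 tol = 1e-3, days_per_year = 365L) {
  horizon_years <- as.integer(horizon_years)
  if (horizon_years < 1L)
    stop("required_extra_input: horizon_years must be >= 1", call. = FALSE)
  n_days <- horizon_years * as.integer(days_per_year)
  base_lab <- rep_len(input_labile, n_days)
  base_res <- rep_len(input_resistant, n_days)
  fe <- rep_len(f_env, n_days)
  s0 <- total_soc(state)
  final_soc <- function(extra) {
    per_day <- extra / days_per_year
    sim <- sim_pools(state, params, fe,
                     base_lab + per_day * split_labile,
                     base_res + per_day * (1 - split_labile),
                     n_days = n_days, days_per_year = days_per_year)
    sum(sim$final[1L, ])
  }
  if (final_soc(0) >= s0) return(0)
  lo <- 0
  hi <- 0.5
  it <- 0L
  while (final_soc(hi) < s0) {
    lo <- hi
    hi <- hi * 2
    it <- it + 1L
    if (it > 40L)
      stop("required_extra_input: failed to bracket the balancing input",
           call. = FALSE)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (final_soc(mid) >= s0) hi <- mid else lo <- mid
  }
  hi
}
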