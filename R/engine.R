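# Internal vectorized daily simulation engine.
#
# One day of the model is: add the day's fresh-residue carbon to the labile
# and resistant pools, decompose every pool by its exact exponential factor
# D_i = C_i * (1 - exp(-K_i * f_env)), route the transfer fractions
# (labile/resistant -> light, light -> heavy), and release the remainder as
# CO2. The heavy pool decomposes to CO2 only. The engine advances an ensemble
# of states (rows) through a shared forcing series in one pass; kinetic
# parameters may be scalars or per-row vectors (used by the calibration grid
# search), and a per-row input scale multiplier supports Monte Carlo input
# uncertainty.

# state0: numeric length 4 (labile, resistant, light, heavy) or n x 4 matrix.
# f_env, input_labile, input_resistant: scalars or length >= n_days vectors.
# scale: per-row multiplier on the daily inputs (length 1 or n).
# record_days: day indices at which to record total SOC.
sim_pools <- function(state0, params, f_env, input_labile, input_resistant,
                      n_days, scale = 1, days_per_year = 365L,
                      record_days = integer(0)) {
  if (!is.matrix(state0)) state0 <- matrix(unclass(state0), nrow = 1L)
  if (ncol(state0) != 4L) stop("sim_pools: state0 must have 4 columns", call. = FALSE)
  if (any(!is.finite(state0))) stop("sim_pools: NaN/Inf in state", call. = FALSE)
  if (any(state0 < 0)) stop("sim_pools: negative pool in state", call. = FALSE)
  n <- nrow(state0)
  n_days <- as.integer(n_days)
  if (n_days < 0L) stop("sim_pools: n_days must be >= 0", call. = FALSE)

  expand_forcing <- function(x, what) {
    if (length(x) == 1L) x <- rep(x, n_days)
    if (length(x) < n_days)
      stop("sim_pools: ", what, " series shorter than n_days", call. = FALSE)
    if (any(!is.finite(x[seq_len(n_days)])))
      stop("sim_pools: non-finite values in ", what, call. = FALSE)
    x
  }
  f_env <- expand_forcing(f_env, "f_env")
  input_labile <- expand_forcing(input_labile, "input_labile")
  input_resistant <- expand_forcing(input_resistant, "input_resistant")
  if (n_days > 0L) {
    if (any(f_env[seq_len(n_days)] < 0))
      stop("sim_pools: f_env must be >= 0", call. = FALSE)
    if (any(input_labile[seq_len(n_days)] < 0) ||
        any(input_resistant[seq_len(n_days)] < 0))
      stop("sim_pools: carbon inputs must be >= 0", call. = FALSE)
  }
  if (length(scale) == 1L) scale <- rep(scale, n)
  if (length(scale) != n) stop("sim_pools: scale length mismatch", call. = FALSE)

  K_L <- params$K_L; K_R <- params$K_R; K_LC <- params$K_LC; K_HC <- params$K_HC
  F_LL <- params$F_LL; F_RL <- params$F_RL; F_LH <- params$F_LH

  L <- state0[, 1L]; Rr <- state0[, 2L]; LC <- state0[, 3L]; HC <- state0[, 4L]

  n_years <- n_days %/% as.integer(days_per_year)
  soc_annual <- matrix(NA_real_, n, n_years)
  co2_annual <- matrix(NA_real_, n, n_years)
  soc_days <- matrix(NA_real_, n, length(record_days))
  rec_idx <- integer(0)
  if (length(record_days)) {
    record_days <- as.integer(record_days)
    if (any(record_days < 1L) || any(record_days > n_days))
      stop("sim_pools: record_days out of range", call. = FALSE)
    rec_idx <- integer(n_days)
    rec_idx[record_days] <- seq_along(record_days)
  }

  co2_total <- numeric(n)
  input_total <- numeric(n)
  co2_year <- numeric(n)
  year <- 0L

  # constant-forcing fast path: precompute the per-day decay complements
  const_f <- n_days > 0L && all(f_env[seq_len(n_days)] == f_env[1L])
  if (const_f) {
    dL <- -expm1(-K_L * f_env[1L]); dR <- -expm1(-K_R * f_env[1L])
    dLC <- -expm1(-K_LC * f_env[1L]); dHC <- -expm1(-K_HC * f_env[1L])
  }

  for (t in seq_len(n_days)) {
    if (!const_f) {
      ft <- f_env[t]
      dL <- -expm1(-K_L * ft); dR <- -expm1(-K_R * ft)
      dLC <- -expm1(-K_LC * ft); dHC <- -expm1(-K_HC * ft)
    }
    bL <- input_labile[t] * scale
    bR <- input_resistant[t] * scale
    L <- L + bL
    Rr <- Rr + bR
    DL <- L * dL; DR <- Rr * dR; DLC <- LC * dLC; DHC <- HC * dHC
    L <- L - DL
    Rr <- Rr - DR
    LC <- LC - DLC + F_LL * DL + F_RL * DR
    HC <- HC - DHC + F_LH * DLC
    co2_day <- (1 - F_LL) * DL + (1 - F_RL) * DR + (1 - F_LH) * DLC + DHC
    co2_total <- co2_total + co2_day
    co2_year <- co2_year + co2_day
    input_total <- input_total + bL + bR
    if (length(rec_idx) && rec_idx[t] > 0L)
      soc_days[, rec_idx[t]] <- L + Rr + LC + HC
    if (n_years > 0L && t %% days_per_year == 0L) {
      year <- year + 1L
      if (year <= n_years) {
        soc_annual[, year] <- L + Rr + LC + HC
        co2_annual[, year] <- co2_year
      }
      co2_year <- numeric(n)
    }
  }

  list(final = cbind(labile = L, resistant = Rr, light = LC, heavy = HC),
       soc_annual = soc_annual, co2_annual = co2_annual,
       soc_days = soc_days, co2_total = co2_total, input_total = input_total)
}
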