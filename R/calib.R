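# Depth harmonisation, model-evaluation statistics and grid-search
# calibration of the five key kinetic parameters.

DEPTH_COEF <- c("0-10" = 2.35, "0-20" = 1.32, "0-30" = 1)

#' Convert an SOC observation to the 0-30 cm layer
#'
#' Observations reported for a shallower layer are scaled by fixed vertical
#' distribution coefficients: 2.35 for 0-10 cm, 1.32 for 0-20 cm; 0-30 cm
#' values pass through unchanged. The shallower the layer, the larger the
#' multiplier.
#'
#' @param value Measured SOC density (Mg C ha^-1); vectorised.
#' @param depth Measurement depth label(s): `"0-10"`, `"0-20"` or `"0-30"`
#'   (cm).
#' @return SOC density in the 0-30 cm layer (Mg C ha^-1).
#' @export
#' @examples
#' soc_to_30cm(10, "0-10")  # 23.5
soc_to_30cm <- function(value, depth) {
  if (any(!is.finite(value)) || any(value < 0))
    stop("soc_to_30cm: value must be non-negative", call. = FALSE)
  depth <- as.character(depth)
  bad <- !depth %in% names(DEPTH_COEF)
  if (any(bad))
    stop("soc_to_30cm: unsupported depth '", depth[bad][1L],
         "' (use 0-10, 0-20 or 0-30)", call. = FALSE)
  unname(value * DEPTH_COEF[depth])
}

check_series <- function(P, O, n_min = 1L) {
  if (length(P) != length(O))
    stop("predicted and observed series must have equal length", call. = FALSE)
  if (length(P) < n_min)
    stop("series must contain at least ", n_min, " values", call. = FALSE)
  if (any(!is.finite(P)) || any(!is.finite(O)))
    stop("series must be finite", call. = FALSE)
  invisible(NULL)
}

#' Mean deviation between predictions and observations
#'
#' `sum(P - O) / n` in absolute units (Mg C ha^-1). The calibration
#' objective is the absolute value of this quantity.
#'
#' @param P Predicted values; @param O observed values (equal length, n >= 1).
#' @return Mean deviation (Mg C ha^-1).
#' @export
mean_deviation <- function(P, O) {
  check_series(P, O)
  mean(P - O)
}

#' Root mean squared error
#'
#' @param P Predicted values; @param O observed values (equal length,
#'   n >= 1).
#' @param normalized If `TRUE`, return the normalised form
#'   `100 / mean(O) * RMSE` (percent of the observed mean) instead of
#'   absolute units.
#' @return RMSE (Mg C ha^-1, or percent when normalised).
#' @export
rmse <- function(P, O, normalized = FALSE) {
  check_series(P, O)
  out <- sqrt(mean((P - O)^2))
  if (normalized) out <- 100 / mean(O) * out
  out
}

#' Relative mean deviation (percent)
#'
#' `100 * sum(P - O) / (n * mean(O))`: the model's systematic bias relative
#' to the observed mean.
#'
#' @param P Predicted values; @param O observed values (equal length, n >= 1,
#'   non-zero observed mean).
#' @return RMD in percent.
#' @export
rmd <- function(P, O) {
  check_series(P, O)
  if (mean(O) == 0) stop("rmd: observed mean is zero", call. = FALSE)
  100 * mean(P - O) / mean(O)
}

#' Nash-Sutcliffe model efficiency
#'
#' `EF = 1 - sum((O - P)^2) / sum((O - mean(O))^2)`: 1 for a perfect model,
#' 0 for a model no better than the observed mean, negative when worse.
#'
#' @param P Predicted values; @param O observed values (equal length, n >= 2,
#'   non-constant O).
#' @return Model efficiency (unitless, <= 1).
#' @export
model_efficiency <- function(P, O) {
  check_series(P, O, n_min = 2L)
  denom <- sum((O - mean(O))^2)
  if (denom == 0)
    stop("model_efficiency: observed series is constant", call. = FALSE)
  1 - sum((O - P)^2) / denom
}

#' Regression evaluation of predictions against observations
#'
#' Ordinary least squares of `P` on `O`, with two-sided t-tests of
#' slope = 1 and intercept = 0 at the 5% level. A model in good agreement
#' has a slope not distinguishable from 1 and an intercept not
#' distinguishable from 0, with high r-squared.
#'
#' @param P Predicted values; @param O observed values (equal length, n >= 3,
#'   non-degenerate O).
#' @param alpha Significance level for the slope/intercept tests (default
#'   0.05).
#' @return List with `slope`, `intercept`, `r_squared`, `n`, the p-values
#'   `p_slope_eq_1` and `p_intercept_eq_0`, and logical decisions
#'   `slope_differs_from_1`, `intercept_differs_from_0`.
#' @export
regression_eval <- function(P, O, alpha = 0.05) {
  check_series(P, O, n_min = 3L)
  if (stats::var(O) == 0)
    stop("regression_eval: observed series has zero variance", call. = FALSE)
  fit <- stats::lm(P ~ O)
  cf <- summary(fit)$coefficients
  df <- fit$df.residual
  t_slope <- (cf["O", "Estimate"] - 1) / cf["O", "Std. Error"]
  p_slope <- 2 * stats::pt(abs(t_slope), df, lower.tail = FALSE)
  p_int <- cf["(Intercept)", "Pr(>|t|)"]
  list(slope = unname(cf["O", "Estimate"]),
       intercept = unname(cf["(Intercept)", "Estimate"]),
       r_squared = summary(fit)$r.squared,
       n = length(P),
       p_slope_eq_1 = unname(p_slope),
       p_intercept_eq_0 = unname(p_int),
       slope_differs_from_1 = unname(p_slope < alpha),
       intercept_differs_from_0 = unname(p_int < alpha))
}

#' Site trial container
#'
#' Bundles one long-term experiment for calibration: the initial pool state,
#' daily forcing, and sparse SOC observations with their measurement depths.
#'
#' @param initial_state A [pool_state()] at day 0 of the trial.
#' @param f_env Daily environmental modifier series (scalar or vector).
#' @param input_labile,input_resistant Daily carbon input series
#'   (Mg C ha^-1 d^-1).
#' @param observations Data frame with columns `day` (1-based simulation day
#'   of the measurement), `value` (Mg C ha^-1) and `depth` (`"0-10"`,
#'   `"0-20"` or `"0-30"`).
#' @param true_params Optional [soc_params()] that generated the trial
#'   (synthetic trials only; used by recovery tests).
#' @return A classed list.
#' @export
site_trial <- function(initial_state, f_env, input_labile, input_resistant,
                       observations, true_params = NULL) {
  need <- c("day", "value", "depth")
  if (!is.data.frame(observations) || !all(need %in% names(observations)))
    stop("site_trial: observations needs columns day, value, depth",
         call. = FALSE)
  if (nrow(observations) == 0L)
    stop("site_trial: no observations", call. = FALSE)
  structure(list(initial_state = initial_state, f_env = f_env,
                 input_labile = input_labile,
                 input_resistant = input_resistant,
                 observations = observations, true_params = true_params),
            class = "site_trial")
}

#' Grid specification for parameter-space search
#'
#' Candidate values for the five key parameters. The defaults bracket the
#' calibrated values (the exact search intervals are a modelling choice).
#'
#' @param K_LC,K_HC Candidate daily rates for the light and heavy pools.
#' @param F_LL,F_RL,F_LH Candidate transfer fractions.
#' @return A classed list of candidate-value vectors.
#' @export
search_spec <- function(K_LC = seq(1e-4, 5e-4, length.out = 9),
                        K_HC = seq(1e-5, 5e-5, length.out = 9),
                        F_LL = seq(0.1, 0.6, length.out = 11),
                        F_RL = seq(0.1, 0.6, length.out = 11),
                        F_LH = seq(0.1, 0.6, length.out = 11)) {
  grids <- list(K_LC = K_LC, K_HC = K_HC, F_LL = F_LL, F_RL = F_RL,
                F_LH = F_LH)
  for (nm in names(grids)) {
    g <- grids[[nm]]
    if (length(g) < 1L || any(!is.finite(g)))
      stop("search_spec: ", nm, " grid must be non-empty and finite",
           call. = FALSE)
    if (nm %in% c("K_LC", "K_HC") && any(g <= 0))
      stop("search_spec: ", nm, " values must be positive", call. = FALSE)
    if (nm %in% c("F_LL", "F_RL", "F_LH") && (any(g < 0) || any(g > 1)))
      stop("search_spec: ", nm, " values must lie in [0, 1]", call. = FALSE)
    grids[[nm]] <- sort(g)
  }
  structure(grids, class = "search_spec")
}

#' Calibrate the five key parameters by exhaustive grid search
#'
#' Evaluates every combination in the Cartesian grid of [search_spec()]
#' values. For each combination the model is run over every trial, predicted
#' SOC is extracted at the observation days, observations are harmonised to
#' 0-30 cm with [soc_to_30cm()], and each trial's mean deviation (predicted
#' minus observed, averaged over that trial's observations) is computed. The
#' objective is the mean absolute per-trial mean deviation: averaging the
#' magnitude site by site prevents a bias at one site cancelling an opposite
#' bias at another. The combination with the smallest objective wins; ties
#' break to the first grid point in lexicographic parameter order (K_LC,
#' K_HC, F_LL, F_RL, F_LH).
#'
#' @param spec A [search_spec()].
#' @param trials Non-empty list of [site_trial()] objects.
#' @param params A [soc_params()] supplying the fixed parameters (K_L, K_R).
#' @param days_per_year Days per simulated year (default 365).
#' @return List with `params` (a [soc_params()] with the winning values),
#'   `objective` (Mg C ha^-1), `mean_deviation` (signed, pooled over all
#'   observations, at the winner) and `grid` (data frame of all combinations
#'   with their objectives).
#' @export
grid_search_calibrate <- function(spec, trials, params = soc_params(),
                                  days_per_year = 365L) {
  if (!inherits(spec, "search_spec")) stop("spec must be a search_spec", call. = FALSE)
  if (!is.list(trials) || length(trials) == 0L)
    stop("grid_search_calibrate: trials must be a non-empty list", call. = FALSE)
  if (inherits(trials, "site_trial")) trials <- list(trials)
  # expand.grid varies its first factor fastest, so list the parameters in
  # reverse to obtain rows sorted lexicographically by (K_LC, K_HC, ...)
  grid <- expand.grid(F_LH = spec$F_LH, F_RL = spec$F_RL, F_LL = spec$F_LL,
                      K_HC = spec$K_HC, K_LC = spec$K_LC,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("K_LC", "K_HC", "F_LL", "F_RL", "F_LH")]
  n_combo <- nrow(grid)
  combo_params <- list(K_L = params$K_L, K_R = params$K_R,
                       K_LC = grid$K_LC, K_HC = grid$K_HC,
                       F_LL = grid$F_LL, F_RL = grid$F_RL, F_LH = grid$F_LH)
  dev_sum <- numeric(n_combo)
  n_obs <- 0L
  trial_dev <- matrix(NA_real_, n_combo, length(trials))
  for (j in seq_along(trials)) {
    trial <- trials[[j]]
    obs <- trial$observations
    obs30 <- soc_to_30cm(obs$value, obs$depth)
    days <- sort(unique(as.integer(obs$day)))
    state0 <- matrix(rep(unclass(trial$initial_state), each = n_combo),
                     nrow = n_combo)
    sim <- sim_pools(state0, combo_params, trial$f_env, trial$input_labile,
                     trial$input_resistant, n_days = max(days),
                     days_per_year = days_per_year, record_days = days)
    pred <- sim$soc_days[, match(as.integer(obs$day), days), drop = FALSE]
    resid <- pred - rep(obs30, each = n_combo)
    trial_dev[, j] <- rowMeans(resid)
    dev_sum <- dev_sum + rowSums(resid)
    n_obs <- n_obs + length(obs30)
  }
  mean_dev <- dev_sum / n_obs  # signed, pooled: the reported bias
  objective <- rowMeans(abs(trial_dev))
  best <- which.min(objective)
  best_params <- soc_params(variant = params$variant,
                            K_L = params$K_L, K_R = params$K_R,
                            K_LC = grid$K_LC[best], K_HC = grid$K_HC[best],
                            F_LL = grid$F_LL[best], F_RL = grid$F_RL[best],
                            F_LH = grid$F_LH[best])
  grid$objective <- objective
  list(params = best_params, objective = objective[best],
       mean_deviation = mean_dev[best], grid = grid)
}
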