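# Pool state and kinetic parameter containers.

DAYS_PER_YEAR_CAL <- 365.25 # calendar year used for rate <-> half-life conversion

#' Four-pool soil carbon state
#'
#' Holds the carbon density (Mg C ha^-1) of the four model pools: the labile
#' and resistant fractions of undecomposed fresh residue, and the light and
#' heavy soil organic carbon sub-pools. Reported SOC density is the total of
#' all four pools in the 0-30 cm layer.
#'
#' @param labile,resistant,light,heavy Pool carbon densities (Mg C ha^-1),
#'   each finite and non-negative.
#' @return A classed numeric vector of length four.
#' @seealso [total_soc()], [step_day()]
#' @export
#' @examples
#' s <- pool_state(light = 7.5, heavy = 22.5)
#' total_soc(s)
pool_state <- function(labile = 0, resistant = 0, light = 0, heavy = 0) {
  x <- c(labile = as.numeric(labile), resistant = as.numeric(resistant),
         light = as.numeric(light), heavy = as.numeric(heavy))
  if (length(x) != 4L || any(!is.finite(x)))
    stop("pool_state: all four pools must be finite scalars", call. = FALSE)
  if (any(x < 0))
    stop("pool_state: pool carbon densities must be non-negative", call. = FALSE)
  structure(x, class = "pool_state")
}

#' Total SOC density of a pool state
#'
#' @param state A [pool_state()].
#' @return Total carbon density (Mg C ha^-1), the sum of the four pools.
#' @export
total_soc <- function(state) {
  sum(unclass(state))
}

#' @export
print.pool_state <- function(x, ...) {
  cat("<pool_state> (Mg C ha^-1)\n")
  print(round(unclass(x), 4))
  cat("total SOC:", format(sum(unclass(x)), digits = 6), "\n")
  invisible(x)
}

#' Decomposition parameters of the four-pool model
#'
#' First-order daily rate constants and inter-pool transfer fractions. The
#' `"modified"` variant is the calibrated default (heavy-C half-life 73 y,
#' F_LH = 0.3); `"original"` keeps the pre-calibration values (heavy-C
#' half-life 105.4 y, F_LH = 0.45). Labile and resistant rates are derived
#' from their half-lives (0.1 y and 2.3 y).
#'
#' @param variant `"modified"` (default) or `"original"` parameter set.
#' @param K_L,K_R,K_LC,K_HC First-order rates (d^-1) for the labile,
#'   resistant, light and heavy pools; must be positive.
#' @param F_LL Fraction of decomposed labile-C routed to light-C.
#' @param F_RL Fraction of decomposed resistant-C routed to light-C.
#' @param F_LH Fraction of decomposed light-C routed to heavy-C.
#' @return A classed list of the seven parameters.
#' @export
#' @examples
#' p <- soc_params()
#' half_life_years(p$K_HC)  # 73 y for the modified heavy pool
soc_params <- function(variant = c("modified", "original"),
                       K_L = rate_from_half_life(0.1),
                       K_R = rate_from_half_life(2.3),
                       K_LC = 2.5e-4,
                       K_HC = NULL,
                       F_LL = 0.3,
                       F_RL = 0.45,
                       F_LH = NULL) {
  variant <- match.arg(variant)
  if (is.null(K_HC)) K_HC <- if (variant == "modified") 2.6e-5 else 1.8e-5
  if (is.null(F_LH)) F_LH <- if (variant == "modified") 0.3 else 0.45
  p <- list(K_L = K_L, K_R = K_R, K_LC = K_LC, K_HC = K_HC,
            F_LL = F_LL, F_RL = F_RL, F_LH = F_LH)
  rates <- unlist(p[c("K_L", "K_R", "K_LC", "K_HC")])
  fracs <- unlist(p[c("F_LL", "F_RL", "F_LH")])
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("soc_params: rate constants must be positive and finite", call. = FALSE)
  if (any(!is.finite(fracs)) || any(fracs < 0) || any(fracs > 1))
    stop("soc_params: transfer fractions must lie in [0, 1]", call. = FALSE)
  structure(c(p, list(variant = variant)), class = "soc_params")
}

#' @export
print.soc_params <- function(x, ...) {
  cat("<soc_params> variant:", x$variant, "\n")
  cat(sprintf("  K_L  = %.4g d^-1 (t1/2 %.2f y)\n", x$K_L, half_life_years(x$K_L)))
  cat(sprintf("  K_R  = %.4g d^-1 (t1/2 %.2f y)\n", x$K_R, half_life_years(x$K_R)))
  cat(sprintf("  K_LC = %.4g d^-1 (t1/2 %.2f y)\n", x$K_LC, half_life_years(x$K_LC)))
  cat(sprintf("  K_HC = %.4g d^-1 (t1/2 %.2f y)\n", x$K_HC, half_life_years(x$K_HC)))
  cat(sprintf("  F_LL = %.3g  F_RL = %.3g  F_LH = %.3g\n", x$F_LL, x$F_RL, x$F_LH))
  invisible(x)
}

#' Half-life of a first-order pool, in years
#'
#' @param K First-order daily rate constant (d^-1), positive.
#' @return Half-life residence time in years, `log(2) / (K * 365.25)`.
#' @export
#' @examples
#' round(half_life_years(2.5e-4), 1)  # 7.6
half_life_years <- function(K) {
  if (any(!is.finite(K)) || any(K <= 0))
    stop("half_life_years: K must be > 0", call. = FALSE)
  log(2) / (K * DAYS_PER_YEAR_CAL)
}

#' Daily rate constant from a half-life in years
#'
#' Inverse of [half_life_years()].
#'
#' @param t_half Half-life residence time (years), positive.
#' @return First-order daily rate constant (d^-1).
#' @export
rate_from_half_life <- function(t_half) {
  if (any(!is.finite(t_half)) || any(t_half <= 0))
    stop("rate_from_half_life: t_half must be > 0", call. = FALSE)
  log(2) / (t_half * DAYS_PER_YEAR_CAL)
}
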