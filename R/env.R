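# Environmental rate modifiers.
#
# The kinetic rate constants apply at modifier value 1. The default mode is
# neutral (modifier identically 1); an optional climate-driven mode combines a
# Q10 temperature response with a rolling-precipitation moisture response,
# both normalised to 1 at the reference temperature and saturated moisture.

#' Environmental modifier configuration
#'
#' @param mode `"neutral"` (modifier identically 1, the default) or
#'   `"climate"` (Q10 temperature response times a linear moisture response).
#' @param q10 Multiplicative change in decomposition rate per 10 degC warming
#'   (unitless, > 0). Default 2.
#' @param t_ref Reference temperature (degC) at which the temperature
#'   response equals 1. Default 20.
#' @param precip_ref Rolling-window precipitation total (mm) at which the
#'   moisture response saturates at 1. Default 60 mm per 30 d.
#' @param precip_window Rolling window length (days) for the moisture proxy.
#' @return A classed list of settings.
#' @export
env_config <- function(mode = c("neutral", "climate"), q10 = 2, t_ref = 20,
                       precip_ref = 60, precip_window = 30L) {
  mode <- match.arg(mode)
  if (!is.finite(q10) || q10 <= 0) stop("env_config: q10 must be > 0", call. = FALSE)
  if (!is.finite(precip_ref) || precip_ref <= 0)
    stop("env_config: precip_ref must be > 0", call. = FALSE)
  precip_window <- as.integer(precip_window)
  if (precip_window < 1L) stop("env_config: precip_window must be >= 1", call. = FALSE)
  structure(list(mode = mode, q10 = q10, t_ref = t_ref,
                 precip_ref = precip_ref, precip_window = precip_window),
            class = "env_config")
}

#' Daily environmental modifier series from a climate record
#'
#' In neutral mode the modifier is exactly 1 for every day. In climate mode
#' the modifier is `f_T * f_W` where `f_T = q10^((T - t_ref)/10)` uses the
#' daily mean temperature `(tmax + tmin)/2`, and `f_W` is the rolling
#' `precip_window`-day precipitation total divided by `precip_ref`, capped at
#' 1. Both responses are non-decreasing in their driver and equal 1 at the
#' reference temperature with saturated moisture.
#'
#' @param climate Data frame with columns `tmax_C`, `tmin_C`, `precip_mm`
#'   (one row per day).
#' @param config An [env_config()].
#' @return Numeric vector of non-negative daily multipliers, one per row.
#' @export
env_modifier <- function(climate, config = env_config()) {
  if (!is.data.frame(climate) || nrow(climate) == 0L)
    stop("env_modifier: climate must be a non-empty data frame", call. = FALSE)
  n <- nrow(climate)
  if (config$mode == "neutral") return(rep(1, n))
  need <- c("tmax_C", "tmin_C", "precip_mm")
  missing_cols <- setdiff(need, names(climate))
  if (length(missing_cols))
    stop("env_modifier: climate lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  tmean <- (climate$tmax_C + climate$tmin_C) / 2
  f_t <- config$q10^((tmean - config$t_ref) / 10)
  w <- config$precip_window
  cs <- cumsum(climate$precip_mm)
  # rolling sum, with a shorter partial window over the first w-1 days
  roll <- cs - c(rep(0, min(w, n)), cs[seq_len(max(0L, n - w))])
  f_w <- pmin(1, roll / config$precip_ref)
  f <- f_t * f_w
  f[f < 0] <- 0
  f
}
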