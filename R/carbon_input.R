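# Yield-driven carbon input: residue ratios, root fraction, carbon content,
# stubble-retention rates and daily scheduling.

#' Carbon-input configuration
#'
#' Converts economic yield into soil carbon input. Above-ground residue mass
#' is `yield * residue_to_yield_ratio`; root mass is `root_fraction *`
#' residue mass; residue and root carbon content is `carbon_content`. The
#' residue-to-yield ratio default of 1.5 corresponds to a wheat harvest index
#' of about 0.4 and is configurable. Fresh residue carbon is split between
#' the labile and resistant pools by `residue_split_labile` (default 0.59
#' labile / 0.41 resistant, the conventional fast/slow split for cereal
#' residue).
#'
#' @param residue_to_yield_ratio Above-ground residue mass per unit economic
#'   yield (unitless, > 0). Default 1.5.
#' @param root_fraction Root mass as a fraction of above-ground residue mass
#'   (default 0.40).
#' @param carbon_content Carbon content of residue and root mass (default
#'   0.45).
#' @param residue_split_labile Fraction of fresh-residue carbon entering the
#'   labile pool (default 0.59).
#' @return A classed list of settings.
#' @export
c_input_config <- function(residue_to_yield_ratio = 1.5, root_fraction = 0.40,
                           carbon_content = 0.45, residue_split_labile = 0.59) {
  if (!is.finite(residue_to_yield_ratio) || residue_to_yield_ratio <= 0)
    stop("c_input_config: residue_to_yield_ratio must be > 0", call. = FALSE)
  fr <- c(root_fraction, carbon_content, residue_split_labile)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1))
    stop("c_input_config: fractions must lie in [0, 1]", call. = FALSE)
  structure(list(residue_to_yield_ratio = residue_to_yield_ratio,
                 root_fraction = root_fraction,
                 carbon_content = carbon_content,
                 residue_split_labile = residue_split_labile),
            class = "c_input_config")
}

#' Annual soil carbon input from crop yield
#'
#' `residue = yield * ratio`; `root = root_fraction * residue`; carbon input
#' is `carbon_content * (retention * residue + root)`. The retention fraction
#' applies to above-ground residue only; roots are always returned to the
#' soil. Manure input is not represented (fixed at zero).
#'
#' @param yield Economic yield (Mg ha^-1 yr^-1, >= 0); vectorised.
#' @param cfg A [c_input_config()].
#' @param retention Fraction of above-ground residue retained in or on the
#'   soil (in `[0, 1]`).
#' @return Annual carbon input (Mg C ha^-1 yr^-1).
#' @export
#' @examples
#' annual_c_input(2.0, c_input_config(), retention = 0.95)  # 1.8225
annual_c_input <- function(yield, cfg = c_input_config(), retention) {
  if (any(!is.finite(yield)) || any(yield < 0))
    stop("annual_c_input: yield must be non-negative", call. = FALSE)
  if (!is.finite(retention) || retention < 0 || retention > 1)
    stop("annual_c_input: retention must lie in [0, 1]", call. = FALSE)
  residue <- yield * cfg$residue_to_yield_ratio
  root <- cfg$root_fraction * residue
  cfg$carbon_content * (retention * residue + root)
}

#' Default stubble-retention table for the five wheat-belt regions
#'
#' Retained fraction of above-ground residue: 0.95 in Queensland (burning
#' essentially abandoned), 0.83 in Western Australia (about 17% burned), and
#' 0.705 in New South Wales, Victoria and South Australia (24-35% burned;
#' midpoint 29.5%). Retention is treated as constant over the simulation
#' period.
#'
#' @return Data frame with columns `region` and `retained_fraction`.
#' @export
default_retention_table <- function() {
  data.frame(region = c("QLD", "NSW", "WA", "SA", "VIC"),
             retained_fraction = c(0.95, 0.705, 0.83, 0.705, 0.705),
             stringsAsFactors = FALSE)
}

#' Look up the retention fraction for a region
#'
#' @param region Region name present in `table`.
#' @param table Data frame with columns `region` and `retained_fraction`
#'   (default [default_retention_table()]).
#' @return The retained fraction (unitless).
#' @export
retention_for_region <- function(region, table = default_retention_table()) {
  i <- match(region, table$region)
  if (is.na(i))
    stop("retention_for_region: unknown region '", region, "'", call. = FALSE)
  v <- table$retained_fraction[i]
  if (!is.finite(v) || v < 0 || v > 1)
    stop("retention_for_region: stored fraction outside [0, 1]", call. = FALSE)
  v
}

#' Spread an annual carbon input over the days of a year
#'
#' @param annual_input Annual carbon input (Mg C ha^-1 yr^-1, >= 0).
#' @param mode `"uniform"` spreads the input evenly over the year;
#'   `"pulse"` places it all on `harvest_day`.
#' @param harvest_day Day of year for pulse mode (1..`days_per_year`).
#' @param days_per_year Days in the scheduled year (default 365).
#' @return Daily series (Mg C ha^-1 d^-1) of length `days_per_year` summing
#'   to `annual_input`.
#' @export
daily_schedule <- function(annual_input, mode = c("uniform", "pulse"),
                           harvest_day = 334L, days_per_year = 365L) {
  mode <- match.arg(mode)
  if (!is.finite(annual_input) || annual_input < 0)
    stop("daily_schedule: annual_input must be >= 0", call. = FALSE)
  days_per_year <- as.integer(days_per_year)
  out <- numeric(days_per_year)
  if (mode == "uniform") {
    out[] <- annual_input / days_per_year
  } else {
    harvest_day <- as.integer(harvest_day)
    if (is.na(harvest_day) || harvest_day < 1L || harvest_day > days_per_year)
      stop("daily_schedule: harvest_day outside 1..", days_per_year, call. = FALSE)
    out[harvest_day] <- annual_input
  }
  out
}

#' Daily labile/resistant input series from annual carbon inputs
#'
#' Schedules each year's carbon input with [daily_schedule()] and splits the
#' fresh-residue carbon between the labile and resistant pools by
#' `cfg$residue_split_labile`.
#'
#' @param annual_inputs Vector of annual carbon inputs (Mg C ha^-1 yr^-1),
#'   one per simulated year.
#' @param cfg A [c_input_config()].
#' @inheritParams daily_schedule
#' @return List with daily series `labile` and `resistant`, each of length
#'   `length(annual_inputs) * days_per_year`.
#' @export
daily_input_series <- function(annual_inputs, cfg = c_input_config(),
                               mode = c("uniform", "pulse"),
                               harvest_day = 334L, days_per_year = 365L) {
  mode <- match.arg(mode)
  daily <- unlist(lapply(annual_inputs, daily_schedule, mode = mode,
                         harvest_day = harvest_day,
                         days_per_year = days_per_year),
                  use.names = FALSE)
  list(labile = daily * cfg$residue_split_labile,
       resistant = daily * (1 - cfg$residue_split_labile))
}
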