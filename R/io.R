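# Configuration files, fixture workspaces, the end-to-end pipeline driver
# and the tabular report writer.

CONFIG_KEYS <- c("seed", "n_runs", "input_halfwidth", "ci_level",
                 "spin_up_years", "env_mode", "params_variant", "regions")
REGION_KEYS <- c("name", "area_Mha", "retained_fraction", "climate", "soil",
                 "yields")

#' Load and validate a pipeline configuration file
#'
#' Reads a YAML configuration, rejects unknown keys (naming them), fills in
#' defaults for optional keys, and records the directory so region file
#' paths resolve relative to the configuration file.
#'
#' @param path Path to a YAML file with top-level keys among `seed`,
#'   `n_runs`, `input_halfwidth`, `ci_level`, `spin_up_years`, `env_mode`,
#'   `params_variant` and a `regions` list whose entries have `name`,
#'   `area_Mha`, `retained_fraction` and the CSV paths `climate`, `soil`,
#'   `yields`.
#' @return A classed list (`run_config`).
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("load_config: no such file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), CONFIG_KEYS)
  if (length(unknown))
    stop("load_config: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(raw$regions) || length(raw$regions) == 0L)
    stop("load_config: 'regions' is required", call. = FALSE)
  cfg <- list(
    seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
    n_runs = if (is.null(raw$n_runs)) 300L else as.integer(raw$n_runs),
    input_halfwidth = if (is.null(raw$input_halfwidth)) 0.10
                      else as.numeric(raw$input_halfwidth),
    ci_level = if (is.null(raw$ci_level)) 0.95 else as.numeric(raw$ci_level),
    spin_up_years = if (is.null(raw$spin_up_years)) 100L
                    else as.integer(raw$spin_up_years),
    env_mode = if (is.null(raw$env_mode)) "neutral" else raw$env_mode,
    params_variant = if (is.null(raw$params_variant)) "modified"
                     else raw$params_variant
  )
  if (!cfg$env_mode %in% c("neutral", "climate"))
    stop("load_config: env_mode must be 'neutral' or 'climate'", call. = FALSE)
  if (!cfg$params_variant %in% c("modified", "original"))
    stop("load_config: params_variant must be 'modified' or 'original'",
         call. = FALSE)
  cfg$regions <- lapply(raw$regions, function(r) {
    unknown <- setdiff(names(r), REGION_KEYS)
    if (length(unknown))
      stop("load_config: unknown region key(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    missing_keys <- setdiff(REGION_KEYS, names(r))
    if (length(missing_keys))
      stop("load_config: region missing key(s): ",
           paste(missing_keys, collapse = ", "), call. = FALSE)
    r$area_Mha <- as.numeric(r$area_Mha)
    r$retained_fraction <- as.numeric(r$retained_fraction)
    r
  })
  cfg$base_dir <- dirname(normalizePath(path))
  structure(cfg, class = "run_config")
}

#' Write a pipeline configuration file
#'
#' Inverse of [load_config()] (up to the recorded `base_dir`).
#'
#' @param cfg A `run_config` list.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  keep <- intersect(names(cfg), CONFIG_KEYS)
  out <- unclass(cfg)[keep]
  out$regions <- lapply(out$regions, function(r) r[REGION_KEYS])
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Materialise a synthetic demonstration workspace
#'
#' Generates the synthetic region set and writes, per region, the climate,
#' soil-grid and yield CSV files plus a top-level `config.yml` ready for
#' [run_regional_analysis()].
#'
#' @param dir Output directory (created if needed).
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed recorded in the configuration.
#' @param n_runs Monte Carlo ensemble size recorded in the configuration.
#' @param with_climate Write per-region climate CSVs (default `TRUE`).
#' @return Path to the written `config.yml`, invisibly.
#' @export
make_fixtures <- function(dir, spec = synthetic_spec(), seed = 1L,
                          n_runs = 300L, with_climate = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  regions <- gen_region_set(spec, seed = seed, with_climate = with_climate)
  region_cfgs <- lapply(regions, function(rg) {
    paths <- list(climate = paste0(rg$name, "_climate.csv"),
                  soil = paste0(rg$name, "_soil.csv"),
                  yields = paste0(rg$name, "_yields.csv"))
    if (with_climate)
      utils::write.csv(rg$climate, file.path(dir, paths$climate),
                       row.names = FALSE)
    utils::write.csv(rg$soil, file.path(dir, paths$soil), row.names = FALSE)
    utils::write.csv(rg$yields, file.path(dir, paths$yields),
                     row.names = FALSE)
    list(name = rg$name, area_Mha = rg$area_Mha,
         retained_fraction = rg$retention,
         climate = paths$climate, soil = paths$soil, yields = paths$yields)
  })
  cfg <- list(seed = as.integer(seed), n_runs = as.integer(n_runs),
              input_halfwidth = 0.10, ci_level = 0.95, spin_up_years = 100L,
              env_mode = "neutral", params_variant = "modified",
              regions = unname(region_cfgs))
  path <- file.path(dir, "config.yml")
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Load one region's inputs from its configuration entry
#'
#' @param rcfg One entry of a `run_config`'s `regions` list.
#' @param base_dir Directory against which the CSV paths resolve.
#' @param with_climate Read the climate CSV (default `TRUE` when present).
#' @return A [region_inputs()].
#' @export
load_region_inputs <- function(rcfg, base_dir = ".", with_climate = TRUE) {
  resolve <- function(p) if (file.exists(p)) p else file.path(base_dir, p)
  soil <- utils::read.csv(resolve(rcfg$soil))
  yields <- utils::read.csv(resolve(rcfg$yields))
  climate <- NULL
  if (with_climate && !is.null(rcfg$climate) &&
      file.exists(resolve(rcfg$climate)))
    climate <- utils::read.csv(resolve(rcfg$climate))
  region_inputs(name = rcfg$name, area_Mha = rcfg$area_Mha, soil = soil,
                yields = yields, retention = rcfg$retained_fraction,
                climate = climate)
}

#' Run the full regional analysis pipeline
#'
#' For every configured region: load inputs, run the Monte Carlo ensemble
#' (region `i` uses seed `seed + i` so the whole analysis is reproducible
#' from the configuration), and summarise by decade; then aggregate to the
#' belt and compute loss rates and shares.
#'
#' @param config Path to a `config.yml` or a `run_config` from
#'   [load_config()].
#' @param n_runs Optional override of the configured ensemble size.
#' @param seed Optional override of the configured seed.
#' @return List with `regions` (per-region `regional_summary`), `belt`
#'   (aggregate summary), `rates` ([loss_rates_and_shares()] of the belt),
#'   `seed` and `n_runs`.
#' @export
run_regional_analysis <- function(config, n_runs = NULL, seed = NULL) {
  cfg <- if (inherits(config, "run_config")) config else load_config(config)
  if (is.null(n_runs)) n_runs <- cfg$n_runs
  if (is.null(seed)) seed <- cfg$seed
  params <- soc_params(variant = cfg$params_variant)
  env <- env_config(mode = cfg$env_mode)
  summaries <- vector("list", length(cfg$regions))
  for (i in seq_along(cfg$regions)) {
    region <- load_region_inputs(cfg$regions[[i]], cfg$base_dir,
                                 with_climate = cfg$env_mode == "climate")
    mc <- monte_carlo_region(
      region, params = params,
      cfg = mc_config(n_runs = n_runs, input_halfwidth = cfg$input_halfwidth,
                      ci_level = cfg$ci_level, seed = seed + i),
      env = env, spin_up_years = cfg$spin_up_years)
    summaries[[i]] <- mc_decadal_summary(mc)
  }
  names(summaries) <- vapply(summaries, function(s) s$region, character(1))
  belt <- aggregate_belt(summaries)
  list(regions = summaries, belt = belt,
       rates = loss_rates_and_shares(belt),
       seed = seed, n_runs = n_runs)
}

#' Flatten an analysis result into a report table
#'
#' One row per region (and the belt) per decade, with confidence bounds as
#' separate columns, plus a `total` row per region.
#'
#' @param result Output of [run_regional_analysis()], or a list of
#'   `regional_summary` objects.
#' @return Data frame with columns `region`, `area_Mha`, `initial_density`,
#'   `decade`, `density`, `density_lo`, `density_hi`, `input`, `change_Tg`,
#'   `change_lo`, `change_hi`.
#' @export
report_table <- function(result) {
  summaries <- if (!is.null(result$regions))
    c(result$regions, list(result$belt)) else result
  rows <- lapply(summaries, function(s) {
    d <- s$decades
    for (col in c("density_lo", "density_hi", "change_lo", "change_hi"))
      if (is.null(d[[col]])) d[[col]] <- NA_real_
    tot <- data.frame(decade = "total", density = NA_real_,
                      density_lo = NA_real_, density_hi = NA_real_,
                      input = NA_real_, change_Tg = s$total_change_Tg,
                      change_lo = if (is.null(s$total_lo)) NA_real_ else s$total_lo,
                      change_hi = if (is.null(s$total_hi)) NA_real_ else s$total_hi,
                      stringsAsFactors = FALSE)
    d <- rbind(d[, names(tot)], tot)
    cbind(region = s$region, area_Mha = s$area_Mha,
          initial_density = s$initial_density, d,
          stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the report CSV
#'
#' @param result Output of [run_regional_analysis()].
#' @param file Output CSV path.
#' @return The report data frame, invisibly.
#' @export
write_report <- function(result, file) {
  tab <- report_table(result)
  utils::write.csv(tab, file, row.names = FALSE)
  invisible(tab)
}

#' Format a mean with its interval in parenthetical style
#'
#' @param mean,lo,hi Numbers to format.
#' @param digits Rounding digits (default 0).
#' @return Character like `"27 (21-33)"`.
#' @export
format_ci <- function(mean, lo, hi, digits = 0) {
  r <- function(x) formatC(round(x, digits), format = "f", digits = digits)
  sprintf("%s (%s-%s)", r(mean), r(lo), r(hi))
}

#' Plain-text summary of the belt-level result
#'
#' @param result Output of [run_regional_analysis()].
#' @return Character vector of summary lines, invisibly; also printed.
#' @export
report_text <- function(result) {
  belt <- result$belt
  rates <- result$rates
  lines <- c(
    sprintf("Belt area: %.2f Mha over %d regions", belt$area_Mha,
            length(result$regions)),
    sprintf("Initial SOC density: %s Mg C ha^-1",
            if (is.null(belt$initial_lo)) sprintf("%.1f", belt$initial_density)
            else format_ci(belt$initial_density, belt$initial_lo, belt$initial_hi)),
    sprintf("Total SOC change: %s Tg C",
            if (is.null(belt$total_lo)) sprintf("%.1f", belt$total_change_Tg)
            else format_ci(belt$total_change_Tg, belt$total_lo, belt$total_hi)),
    sprintf("Mean annual rate: %.2f Tg yr^-1",
            rates$mean_annual_rate_Tg_per_yr),
    paste0("Decadal rates (Tg yr^-1): ",
           paste(sprintf("%s %.1f", rates$decade, rates$rate_Tg_per_yr),
                 collapse = ", ")),
    paste0("Decadal shares of total change (%): ",
           paste(sprintf("%s %.1f", rates$decade, rates$share_pct),
                 collapse = ", ")))
  cat(lines, sep = "\n")
  invisible(lines)
}
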