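#' Configuration for a full pipeline run
#'
#' @param synthetic A [synthetic_config()]; inputs are generated from it
#'   unless `paths` is given.
#' @param paths Optional named list of input files (`urban`, `non_urban`,
#'   `population`, `boundary`, `mortality`, `pollution`, `stations`)
#'   written in the package's text formats; when present these are read
#'   instead of generated.
#' @param erf An [exposure_response()] for heat; `NULL` derives one from
#'   the synthetic planted coefficients with a +/-15% default
#'   coefficient interval (standing in for literature-derived
#'   uncertainty).
#' @param pollutant_coefs Named list per pollutant:
#'   `list(percent_per_10 = , ci = c(low, high))`. Defaults are the
#'   standard urban-background coefficients: ozone 0.34% (0.12-0.56)
#'   and PM2.5 1.04% (0.52-1.56) per 10 ug/m3.
#' @param period Optional `c(start, end)` Dates; default: all days with
#'   a complete 0-2 day lag window.
#' @param boundary Optional (lon, lat) ring; default: a rectangle inset
#'   one cell from the grid edge.
#' @param out_dir Optional output directory for the report bundle.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            paths = NULL,
                            erf = NULL,
                            pollutant_coefs = list(
                              ozone = list(percent_per_10 = 0.34, ci = c(0.12, 0.56)),
                              pm25 = list(percent_per_10 = 1.04, ci = c(0.52, 1.56))),
                            period = NULL,
                            boundary = NULL,
                            out_dir = NULL) {
  structure(list(synthetic = synthetic, paths = paths, erf = erf,
                 pollutant_coefs = pollutant_coefs, period = period,
                 boundary = boundary, out_dir = out_dir),
            class = "pipeline_config")
}

default_erf <- function(cfg, rel_ci = 0.15) {
  exposure_response(cfg$planted_threshold, data.frame(
    stratum = names(cfg$planted_beta),
    central = unname(cfg$planted_beta),
    low = unname(cfg$planted_beta) * (1 - rel_ci),
    high = unname(cfg$planted_beta) * (1 + rel_ci)))
}

#' Default analysis boundary for a grid
#'
#' A rectangle inset one cell from the grid edge, so the outermost ring
#' of cells falls outside the study region (mirroring a city boundary
#' sitting inside the model domain).
#'
#' @param grid A [reg_grid()].
#' @return Two-column (lon, lat) vertex matrix.
#' @export
default_boundary <- function(grid) {
  xe <- grid_x_edges(grid); ye <- grid_y_edges(grid)
  # rectangle inset by one cell, so edge cells fall outside the region
  rbind(c(xe[2], ye[2]), c(xe[grid$nx], ye[2]),
        c(xe[grid$nx], ye[grid$ny]), c(xe[2], ye[grid$ny]), c(xe[2], ye[2]))
}

collect_inputs <- function(config) {
  cfg <- config$synthetic
  if (!is.null(config$paths)) {
    p <- config$paths
    urban <- read_gridded(p$urban)
    non_urban <- read_gridded(p$non_urban)
    pop <- read_population(p$population)
    boundary <- read_boundary_geojson(p$boundary)
    mortality <- read_mortality_csv(p$mortality)
    pollution <- read_pollution_csv(p$pollution)
    stations <- read_stations_csv(p$stations)
    truth <- NULL
  } else {
    fields <- gen_temperature_grids(cfg)
    urban <- fields$urban; non_urban <- fields$non_urban
    pop <- gen_population_grid(cfg)
    boundary <- config$boundary %||% default_boundary(urban$grid)
    mask <- make_region_mask(boundary, urban$grid)
    exp_urban <- lag_mean(daily_aggregate(
      population_weighted_series(urban, pop, mask), "mean", cfg$utc_offset))
    gm <- gen_mortality(exp_urban, cfg)
    mortality <- gm$mortality; truth <- gm$truth
    pollution <- gen_pollution(population_weighted_series(urban, pop, mask), cfg)
    stations <- gen_stations(urban, non_urban, cfg)
  }
  list(urban = urban, non_urban = non_urban, pop = pop,
       boundary = config$boundary %||% default_boundary(urban$grid),
       mortality = mortality, truth = truth,
       pollution = pollution, stations = stations)
}

#' Write a full set of synthetic pipeline inputs to disk
#'
#' Produces the same formats the ingestion functions read, so a
#' file-based run can be checked against an in-memory run.
#'
#' @param config A [pipeline_config()].
#' @param dir Output directory.
#' @return Named list of paths suitable for `pipeline_config(paths=)`.
#' @export
write_pipeline_inputs <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  inp <- collect_inputs(config)
  paths <- list(urban = file.path(dir, "urban.csv"),
                non_urban = file.path(dir, "non_urban.csv"),
                population = file.path(dir, "population.csv"),
                boundary = file.path(dir, "boundary.geojson"),
                mortality = file.path(dir, "mortality.csv"),
                pollution = file.path(dir, "pollution.csv"),
                stations = file.path(dir, "stations.csv"))
  write_gridded(inp$urban, paths$urban, units = "K")
  write_gridded(inp$non_urban, paths$non_urban, units = "K")
  write_population(inp$pop, paths$population)
  write_boundary_geojson(inp$boundary, paths$boundary)
  write_mortality_csv(inp$mortality, paths$mortality)
  write_pollution_csv(inp$pollution, paths$pollution)
  write_stations_csv(inp$stations, paths$stations)
  paths
}

#' Run the full attribution pipeline
#'
#' Chains exposure construction (population-weighted series per
#' scenario, daily means, 0-2 day lag), heat attribution per scenario,
#' UHI attribution as the paired difference, pollutant attribution from
#' the daily maximum 8-hour running mean, UHII summary statistics and
#' station validation, and assembles the report bundle. Deterministic
#' given the config (all randomness flows from the synthetic seed).
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result`: `exposure` (per-scenario
#'   lagged series), `heat` (urban/non_urban/uhi attribution results),
#'   `pollutants` (per-pollutant attribution), `uhii`, `validation`
#'   (per-station and network summaries), `table1`, `daily_af`,
#'   `truth`, `period`. If `config$out_dir` is set the bundle is also
#'   written as CSV/JSON reports.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config$synthetic
  inp <- collect_inputs(config)
  mask <- make_region_mask(inp$boundary, inp$urban$grid)

  hourly <- list(urban = population_weighted_series(inp$urban, inp$pop, mask),
                 non_urban = population_weighted_series(inp$non_urban, inp$pop, mask))
  lagged <- lapply(hourly, function(h)
    lag_mean(daily_aggregate(h, "mean", cfg$utc_offset)))

  period <- config$period %||% range(lagged$urban$date)
  erf <- config$erf %||% default_erf(cfg)

  heat_urban <- attribute_heat(lagged$urban, inp$mortality, erf, period)
  heat_non_urban <- attribute_heat(lagged$non_urban, inp$mortality, erf, period)
  uhi <- attribute_uhi(heat_urban, heat_non_urban)

  pollutants <- list()
  for (p in unique(inp$pollution$pollutant)) {
    co <- config$pollutant_coefs[[p]]
    if (is.null(co)) next
    conc <- inp$pollution[inp$pollution$pollutant == p, ]
    hourly_conc <- exposure_series(
      data.frame(time = conc$time, value = conc$concentration_ugm3),
      metric = "hourly_raw", units = "ugm3", scenario = p)
    daily_conc <- daily_max_8h_running_mean(hourly_conc, cfg$utc_offset)
    pollutants[[p]] <- attribute_pollutant(daily_conc, inp$mortality,
                                           co$percent_per_10, co$ci, period)
  }

  uhii <- uhii_stats(inp$urban, inp$non_urban, inp$pop, mask, cfg$utc_offset)

  per_station <- rbind(validate_stations(inp$stations, inp$urban),
                       validate_stations(inp$stations, inp$non_urban))
  networks <- network_summary(per_station)

  t1 <- make_table1(heat_urban, heat_non_urban, uhi, inp$mortality, period)
  daf <- daily_af_table(heat_urban, pollutants)

  res <- structure(
    list(exposure = lagged, heat = list(urban = heat_urban,
                                        non_urban = heat_non_urban, uhi = uhi),
         pollutants = pollutants, uhii = uhii,
         validation = list(per_station = per_station, networks = networks),
         table1 = t1, daily_af = daf, truth = inp$truth, period = period,
         erf = erf),
    class = "pipeline_result")
  if (!is.null(config$out_dir)) write_report_bundle(res, config$out_dir, config)
  res
}

#' Table of attributable deaths by scenario and age group
#'
#' The report table: rows Urban, Non-urban, UHI and Total mortality;
#' columns total plus the age strata, each cell carrying central and
#' 95% interval. The UHI row is the paired urban minus non-urban
#' difference computed before any rounding; rounding to whole deaths
#' happens only at the formatting layer.
#'
#' @param urban,non_urban,uhi [attribute_heat()] / [attribute_uhi()]
#'   results.
#' @param mortality Mortality data.frame (for the Total mortality row).
#' @param period `c(start, end)` Dates for the mortality denominator.
#' @return data.frame `scenario`, `stratum`, `central`, `low`, `high`.
#' @export
make_table1 <- function(urban, non_urban, uhi, mortality, period) {
  one <- function(res, label) {
    tot <- res$totals
    by <- res$totals_by_stratum
    rows <- rbind(
      data.frame(stratum = "total",
                 central = tot$attributable_deaths[tot$quantile == "central"],
                 low = tot$attributable_deaths[tot$quantile == "low"],
                 high = tot$attributable_deaths[tot$quantile == "high"]),
      do.call(rbind, lapply(sort(unique(by$stratum)), function(a) {
        g <- by[by$stratum == a, ]
        data.frame(stratum = a,
                   central = g$attributable_deaths[g$quantile == "central"],
                   low = g$attributable_deaths[g$quantile == "low"],
                   high = g$attributable_deaths[g$quantile == "high"])
      })))
    cbind(scenario = label, rows)
  }
  days <- seq(as.Date(period[1]), as.Date(period[2]), by = "day")
  m <- mortality[mortality$date %in% days & mortality$age_group != "all", ]
  mrow <- stats::aggregate(deaths ~ age_group, m, sum)
  mort_rows <- data.frame(scenario = "Total mortality",
                          stratum = c("total", mrow$age_group),
                          central = c(sum(mrow$deaths), mrow$deaths),
                          low = NA_real_, high = NA_real_)
  out <- rbind(one(urban, "Urban"), one(non_urban, "Non-urban"),
               one(uhi, "UHI"), mort_rows)
  rownames(out) <- NULL
  out
}

#' Consistency checks and derived percentages for a report table
#'
#' Verifies the arithmetic a reader can do on the printed table — age
#' columns summing to the total column per scenario, the UHI row
#' equalling urban minus non-urban — and derives the headline
#' percentages (heat-attributable share of all deaths, UHI share of
#' heat deaths and of all deaths, pollutant shares, heat-to-ozone
#' ratio), rounded half-to-even to the printed precision.
#'
#' @param t1 A [make_table1()]-shaped data.frame (`scenario`,
#'   `stratum`, `central`).
#' @param ozone_total,pm25_total Pollutant-attributable totals.
#' @param tol Absolute tolerance for the pre-rounding identities.
#' @param uhi_tol Tolerance for the UHI = urban - non-urban identity.
#'   On a machine-precision table this is `tol`; on a table of printed
#'   integers the difference was taken before rounding, so each entry
#'   can be off by up to 1.5 (three independent half-unit roundings).
#' @return List: `checks` (named logical) and `derived` (named numeric
#'   rounded percentages/ratio).
#' @export
table1_consistency <- function(t1, ozone_total = NA, pm25_total = NA, tol = 1e-6,
                               uhi_tol = tol) {
  val <- function(scn, str) {
    v <- t1$central[t1$scenario == scn & t1$stratum == str]
    if (!length(v)) NA_real_ else v
  }
  strata <- setdiff(unique(t1$stratum), "total")
  sums_ok <- vapply(unique(t1$scenario), function(s) {
    abs(sum(vapply(strata, function(a) val(s, a), numeric(1))) -
          val(s, "total")) <= tol
  }, logical(1))
  uhi_ok <- all(vapply(c("total", strata), function(a) {
    abs((val("Urban", a) - val("Non-urban", a)) - val("UHI", a)) <= uhi_tol
  }, logical(1)))
  tm <- val("Total mortality", "total")
  heat <- val("Urban", "total"); uhit <- val("UHI", "total")
  derived <- c(
    pct_heat_of_total = round(100 * heat / tm),
    pct_uhi_of_heat = round(100 * uhit / heat),
    pct_uhi_of_total = round(100 * uhit / tm),
    pct_ozone_of_total = round(100 * ozone_total / tm),
    pct_pm25_of_total = round(100 * pm25_total / tm),
    ratio_heat_to_ozone = round(heat / ozone_total))
  list(checks = c(stats::setNames(sums_ok, paste0("sum_", unique(t1$scenario))),
                  uhi_is_difference = uhi_ok),
       derived = derived)
}

#' Daily attributable-fraction series across exposures
#'
#' One row per analysis day: total recorded deaths, the heat
#' attributable fraction (all-ages, central), and per-pollutant
#' attributable fractions — the report's daily comparison of heat
#' versus air-pollution burden.
#'
#' @param heat_urban Heat attribution result (urban scenario).
#' @param pollutants Named list of pollutant attribution results.
#' @return data.frame `date`, `deaths`, `af_heat`, then one `af_<p>`
#'   column per pollutant.
#' @export
daily_af_table <- function(heat_urban, pollutants) {
  d <- heat_urban$daily
  cen <- d[d$quantile == "central", ]
  deaths <- stats::aggregate(deaths ~ date, cen, sum)
  ad <- stats::aggregate(attributable_deaths ~ date, cen, sum)
  out <- data.frame(date = deaths$date, deaths = deaths$deaths,
                    af_heat = ad$attributable_deaths / deaths$deaths)
  for (p in names(pollutants)) {
    pd <- pollutants[[p]]$daily
    pc <- pd[pd$quantile == "central", ]
    out[[paste0("af_", p)]] <-
      pc$attributable_fraction[match(out$date, pc$date)]
  }
  out
}

write_report_bundle <- function(res, out_dir, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE, quote = FALSE)

  for (s in names(res$heat)) {
    r <- res$heat[[s]]
    daily <- r$daily[, c("date", "stratum", "quantile",
                         "attributable_deaths", "attributable_fraction")]
    names(daily)[1] <- "day"
    daily$day <- as.character(daily$day)
    totals <- cbind(day = "total", r$totals_by_stratum[
      , c("stratum", "quantile", "attributable_deaths")],
      attributable_fraction = NA)
    wcsv(rbind(daily, totals), paste0("attribution_", s, ".csv"))
  }
  for (p in names(res$pollutants)) {
    r <- res$pollutants[[p]]
    daily <- r$daily[, c("date", "stratum", "quantile",
                         "attributable_deaths", "attributable_fraction")]
    names(daily)[1] <- "day"
    wcsv(daily, paste0("attribution_pollutant_", p, ".csv"))
  }
  wcsv(res$table1, "table1.csv")
  wcsv(res$daily_af, "daily_attributable_fraction.csv")
  wcsv(data.frame(stat = c("min", "mean", "max"),
                  uhii_degC = c(res$uhii$min, res$uhii$mean, res$uhii$max)),
       "uhii_summary.csv")
  wcsv(res$validation$per_station, "validation_stations.csv")
  wcsv(res$validation$networks, "validation_networks.csv")

  totals_json <- list(
    period = as.character(res$period),
    heat = lapply(res$heat, function(r)
      stats::setNames(as.list(r$totals$attributable_deaths), r$totals$quantile)),
    pollutants = lapply(res$pollutants, function(r)
      stats::setNames(as.list(r$totals$attributable_deaths), r$totals$quantile)),
    uhii = list(min = res$uhii$min, mean = res$uhii$mean, max = res$uhii$max))
  jsonlite::write_json(totals_json, file.path(out_dir, "totals.json"),
                       auto_unbox = TRUE, digits = NA)

  manifest <- list(seed = config$synthetic$seed,
                   n_days = config$synthetic$n_days,
                   period = as.character(res$period),
                   n_analysis_days = nrow(res$daily_af),
                   n_stations = nrow(unique(res$validation$per_station["station_id"])),
                   strata = unique(res$table1$stratum))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
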