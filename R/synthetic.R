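#' Configuration for the synthetic study generator
#'
#' Generates every input the analysis consumes — two-scenario gridded
#' temperature, population, daily mortality with a planted threshold
#' log-linear temperature effect, temperature-correlated pollutant
#' concentrations, and two station networks — with known ground truth.
#' Defaults emulate a ~16-day mid-July heatwave over a city of ~8.8
#' million where the urban/non-urban difference is concentrated at night
#' and at the city centre.
#'
#' @param grid_shape `(ny, nx)` cells.
#' @param cell_size Cell size in degrees.
#' @param origin `(lon, lat)` of the lower-left cell centre.
#' @param n_days Length of the simulated period (>= 5: two lag warm-up
#'   days plus at least three analysable days).
#' @param start_date First simulated day.
#' @param heatwave_peak_day Day index of the heatwave peak.
#' @param base_daily_mean Baseline daily-mean temperature, degC.
#' @param diurnal_amplitude Half-range of the diurnal cycle, degC.
#' @param heatwave_amplitude Peak heatwave anomaly, degC.
#' @param heatwave_width_days Gaussian width of the heatwave pulse, days.
#' @param synoptic_sd,synoptic_rho SD (degC) and lag-1 autocorrelation of
#'   the day-to-day synoptic anomaly (gives the exposure series the
#'   day-to-day variation a regression needs).
#' @param uhii_night_peak Urban minus non-urban difference at the city
#'   centre at night, degC (>= 0).
#' @param uhii_day_peak Daytime centre difference, degC; may be negative
#'   (the non-urban scenario can run warmer by day).
#' @param uhii_length_scale Gaussian radius of the UHI surface, cells.
#' @param noise_sd SD of independent cell-hour noise added to the urban
#'   field, degC.
#' @param population List: `total` persons, `profile` one of
#'   `"gaussian"`, `"uniform"`, `"point"`, and Gaussian `length_scale`
#'   in cells.
#' @param baseline_deaths_per_day Named per-stratum expected deaths per
#'   day at or below the threshold.
#' @param planted_beta Named per-stratum log relative risk per degC
#'   above the threshold.
#' @param planted_threshold Threshold, degC.
#' @param pollutants Named list per pollutant: `intercept` (ug/m3),
#'   `slope` (ug/m3 per degC of hourly regional temperature),
#'   `noise_sd`.
#' @param stations List: `n_official`, `n_pws`, `official_noise_sd`,
#'   `pws_noise_sd`, `official_bias_sd`, `pws_bias_sd` (per-station
#'   fixed offset SD, degC).
#' @param utc_offset Hours added to UTC to define the local civil day.
#' @param seed Global seed; fanned out to per-component substreams.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(grid_shape = c(20L, 20L),
                             cell_size = 0.01,
                             origin = c(-0.2, 51.4),
                             n_days = 16L,
                             start_date = as.Date("2022-07-10"),
                             heatwave_peak_day = 10L,
                             base_daily_mean = 21,
                             diurnal_amplitude = 5.5,
                             heatwave_amplitude = 10,
                             heatwave_width_days = 2.5,
                             synoptic_sd = 1.2,
                             synoptic_rho = 0.6,
                             uhii_night_peak = 7,
                             uhii_day_peak = -0.5,
                             uhii_length_scale = 8,
                             noise_sd = 0.4,
                             population = list(total = 8.8e6,
                                               profile = "gaussian",
                                               length_scale = 5),
                             baseline_deaths_per_day = c("0-64" = 31, "65-74" = 24,
                                                         "75plus" = 93),
                             planted_beta = c("0-64" = 0.025, "65-74" = 0.030,
                                              "75plus" = 0.040),
                             planted_threshold = 18.9,
                             pollutants = list(
                               ozone = list(intercept = 20, slope = 2.2, noise_sd = 6),
                               pm25 = list(intercept = 4, slope = 0.45, noise_sd = 1.5)),
                             stations = list(n_official = 6L, n_pws = 24L,
                                             official_noise_sd = 0.5,
                                             pws_noise_sd = 2.0,
                                             official_bias_sd = 0,
                                             pws_bias_sd = 1.0),
                             utc_offset = 0,
                             seed = 1L) {
  cfg <- list(grid_shape = as.integer(grid_shape), cell_size = cell_size,
              origin = origin, n_days = as.integer(n_days),
              start_date = as.Date(start_date),
              heatwave_peak_day = heatwave_peak_day,
              base_daily_mean = base_daily_mean,
              diurnal_amplitude = diurnal_amplitude,
              heatwave_amplitude = heatwave_amplitude,
              heatwave_width_days = heatwave_width_days,
              synoptic_sd = synoptic_sd, synoptic_rho = synoptic_rho,
              uhii_night_peak = uhii_night_peak, uhii_day_peak = uhii_day_peak,
              uhii_length_scale = uhii_length_scale, noise_sd = noise_sd,
              population = population,
              baseline_deaths_per_day = baseline_deaths_per_day,
              planted_beta = planted_beta,
              planted_threshold = planted_threshold,
              pollutants = pollutants, stations = stations,
              utc_offset = utc_offset, seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  if (any(cfg$grid_shape < 1L)) stop("degenerate grid: grid_shape must be positive")
  if (cfg$n_days < 5L) stop("n_days must be >= 5 (2 lag warm-up days + 3 analysable)")
  nonneg <- c(diurnal_amplitude = cfg$diurnal_amplitude,
              heatwave_amplitude = cfg$heatwave_amplitude,
              uhii_night_peak = cfg$uhii_night_peak,
              noise_sd = cfg$noise_sd, synoptic_sd = cfg$synoptic_sd)
  bad <- names(nonneg)[nonneg < 0]
  if (length(bad)) stop("negative amplitude(s): ", paste(bad, collapse = ", "))
  if (any(cfg$baseline_deaths_per_day < 0)) stop("negative baseline mortality rate")
  if (!identical(names(cfg$baseline_deaths_per_day), names(cfg$planted_beta)))
    stop("baseline_deaths_per_day and planted_beta must share stratum names")
  invisible(cfg)
}

synthetic_grid <- function(cfg) {
  reg_grid(cfg$origin[1], cfg$origin[2],
           nx = cfg$grid_shape[2], ny = cfg$grid_shape[1], dx = cfg$cell_size)
}

synthetic_times <- function(cfg) {
  t0 <- as.POSIXct(paste(cfg$start_date, "00:00:00"), tz = "UTC")
  t0 + 3600 * (seq_len(cfg$n_days * 24L) - 1L)
}

# Diurnal cycle with minimum at 05:00 and maximum at 15:00 local: a
# piecewise-phase cosine (a single sinusoid cannot place both extrema).
diurnal_shape <- function(hour) {
  h <- hour %% 24
  p <- ifelse(h >= 5 & h < 15, (h - 5) / 10, 1 + ((h - 15) %% 24) / 14)
  -cos(pi * p)
}

# Weight of the nighttime UHII amplitude: 1 deep in the night
# (20:00-08:00), 0 deep in the day, 2-hour linear ramps across the
# 08:00 and 20:00 boundaries.
night_weight <- function(hour) {
  h <- hour %% 24
  ifelse(h >= 7 & h <= 9, (9 - h) / 2,
         ifelse(h >= 19 & h <= 21, (h - 19) / 2,
                ifelse(h > 21 | h < 7, 1, 0)))
}

# Gaussian radial surface in cell units around the grid centre
radial_surface <- function(grid, length_scale) {
  cx <- (grid$nx + 1) / 2
  cy <- (grid$ny + 1) / 2
  ix <- matrix(rep(seq_len(grid$nx), each = grid$ny), grid$ny, grid$nx)
  iy <- matrix(rep(seq_len(grid$ny), grid$nx), grid$ny, grid$nx)
  r <- sqrt((ix - cx)^2 + (iy - cy)^2)
  exp(-0.5 * (r / length_scale)^2)
}

#' Generate the urban and counterfactual non-urban temperature fields
#'
#' The non-urban field is a spatially uniform base climate: diurnal
#' cycle plus a Gaussian heatwave pulse centred on `heatwave_peak_day`
#' plus an AR(1) day-to-day synoptic anomaly. The urban field adds a UHI
#' surface — Gaussian radial decay from the grid centre whose amplitude
#' interpolates between the daytime and nighttime peaks — plus
#' independent cell-hour noise.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `urban` and `non_urban` [grid_series()] on a shared
#'   grid and time axis. Deterministic given `cfg$seed`.
#' @export
gen_temperature_grids <- function(cfg) {
  validate_synthetic_config(cfg)
  grid <- synthetic_grid(cfg)
  times <- synthetic_times(cfg)
  nt <- length(times)
  hour <- (as.numeric(times) / 3600) %% 24 + cfg$utc_offset
  day_index <- rep(seq_len(cfg$n_days), each = 24L)

  set.seed(substream_seed(cfg$seed, "synoptic"))
  syn <- numeric(cfg$n_days)
  if (cfg$synoptic_sd > 0) {
    innov_sd <- cfg$synoptic_sd * sqrt(1 - cfg$synoptic_rho^2)
    syn[1] <- stats::rnorm(1, 0, cfg$synoptic_sd)
    for (d in seq_len(cfg$n_days)[-1])
      syn[d] <- cfg$synoptic_rho * syn[d - 1] + stats::rnorm(1, 0, innov_sd)
  }

  pulse <- cfg$heatwave_amplitude *
    exp(-0.5 * ((seq_len(cfg$n_days) - cfg$heatwave_peak_day) / cfg$heatwave_width_days)^2)
  base_hourly <- cfg$base_daily_mean + syn[day_index] + pulse[day_index] +
    cfg$diurnal_amplitude * diurnal_shape(hour)

  ncell <- grid$ny * grid$nx
  non_urban_vals <- array(rep(base_hourly, ncell), dim = c(nt, grid$ny, grid$nx))

  surf <- radial_surface(grid, cfg$uhii_length_scale)
  amp <- cfg$uhii_day_peak +
    (cfg$uhii_night_peak - cfg$uhii_day_peak) * night_weight(hour)
  uhii <- outer(amp, surf)                       # (nt, ny, nx)
  urban_vals <- non_urban_vals + uhii
  if (cfg$noise_sd > 0) {
    set.seed(substream_seed(cfg$seed, "uhii_noise"))
    urban_vals <- urban_vals + array(stats::rnorm(nt * ncell, 0, cfg$noise_sd),
                                     dim = dim(urban_vals))
  }
  list(urban = grid_series(urban_vals, times, grid, "urban"),
       non_urban = grid_series(non_urban_vals, times, grid, "non-urban"))
}

#' Generate a population grid
#'
#' @param cfg A [synthetic_config()].
#' @param profile Overrides `cfg$population$profile`: `"gaussian"`
#'   (default; population concentrated toward the centre so weighting
#'   differs from the plain mean), `"uniform"`, or `"point"` (all
#'   persons in the centre cell).
#' @return A [population_grid()].
#' @export
gen_population_grid <- function(cfg, profile = NULL) {
  validate_synthetic_config(cfg)
  grid <- synthetic_grid(cfg)
  profile <- profile %||% cfg$population$profile
  total <- cfg$population$total
  counts <- switch(profile,
    uniform = matrix(total / (grid$ny * grid$nx), grid$ny, grid$nx),
    point = {
      m <- matrix(0, grid$ny, grid$nx)
      m[ceiling(grid$ny / 2), ceiling(grid$nx / 2)] <- total
      m
    },
    gaussian = {
      k <- radial_surface(grid, cfg$population$length_scale)
      k / sum(k) * total
    },
    stop("unknown population profile: ", profile))
  population_grid(counts, grid)
}

#' Generate daily mortality with a planted heat effect
#'
#' Deaths per stratum and day are Poisson with mean
#' `baseline * exp(beta * max(0, X_d - threshold))` where `X_d` is the
#' supplied daily exposure (intended: the 0-2 day lag mean). The
#' returned ground truth carries the analytic expected attributable
#' count `sum_d baseline * (RR_d - 1)` and its sampling variance
#' `sum_d AF_d^2 * lambda_d`, enabling parameter-recovery and
#' Monte-Carlo envelope checks.
#'
#' @param exposure A daily [exposure_series()] with no gaps.
#' @param cfg A [synthetic_config()].
#' @return List with `mortality` (data.frame `date`, `age_group`,
#'   `deaths`) and `truth` (list: `planted_beta`, `planted_threshold`,
#'   `expected_attributable`, `var_attributable`, per-stratum
#'   breakdowns).
#' @export
gen_mortality <- function(exposure, cfg) {
  validate_synthetic_config(cfg)
  stopifnot("date" %in% names(exposure))
  d <- diff(as.integer(exposure$date))
  if (length(d) && any(d != 1L)) stop("exposure series has gaps")
  if (any(cfg$baseline_deaths_per_day < 0)) stop("negative baseline mortality rate")

  strata <- names(cfg$baseline_deaths_per_day)
  excess <- pmax(0, exposure$value - cfg$planted_threshold)
  set.seed(substream_seed(cfg$seed, "mortality"))
  rows <- lapply(strata, function(a) {
    lam <- cfg$baseline_deaths_per_day[[a]] * exp(cfg$planted_beta[[a]] * excess)
    data.frame(date = exposure$date, age_group = a,
               deaths = stats::rpois(length(lam), lam))
  })
  mortality <- do.call(rbind, rows)
  rownames(mortality) <- NULL

  exp_by <- vapply(strata, function(a) {
    rr <- exp(cfg$planted_beta[[a]] * excess)
    sum(cfg$baseline_deaths_per_day[[a]] * (rr - 1))
  }, numeric(1))
  var_by <- vapply(strata, function(a) {
    rr <- exp(cfg$planted_beta[[a]] * excess)
    lam <- cfg$baseline_deaths_per_day[[a]] * rr
    af <- (rr - 1) / rr
    sum(af^2 * lam)
  }, numeric(1))
  truth <- list(planted_beta = cfg$planted_beta,
                planted_threshold = cfg$planted_threshold,
                expected_attributable = sum(exp_by),
                expected_by_stratum = exp_by,
                var_attributable = sum(var_by),
                var_by_stratum = var_by)
  list(mortality = mortality, truth = truth)
}

#' Generate hourly pollutant concentrations tied to temperature
#'
#' `concentration = intercept + slope * T_hour + noise`, floored at 0,
#' per pollutant — hot days carry higher ozone and PM2.5.
#'
#' @param temperature An hourly [exposure_series()] in degC.
#' @param cfg A [synthetic_config()].
#' @return data.frame `time`, `pollutant`, `concentration_ugm3`.
#' @export
gen_pollution <- function(temperature, cfg) {
  validate_synthetic_config(cfg)
  stopifnot("time" %in% names(temperature))
  out <- lapply(names(cfg$pollutants), function(p) {
    spec <- cfg$pollutants[[p]]
    set.seed(substream_seed(cfg$seed, paste0("pollution/", p)))
    noise <- if (spec$noise_sd > 0)
      stats::rnorm(nrow(temperature), 0, spec$noise_sd) else 0
    conc <- pmax(0, spec$intercept + spec$slope * temperature$value + noise)
    data.frame(time = temperature$time, pollutant = p, concentration_ugm3 = conc)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate synthetic station networks
#'
#' Official stations sit at grid-edge cells where the UHI surface is
#' near zero (a non-urban-like environment) and observe with small
#' noise; personal weather stations (PWS) sit at central cells with
#' larger noise plus a fixed per-station bias. Both observe the urban
#' scenario (the "real" atmosphere). Each record stores its source cell
#' and every injected perturbation, so validation statistics can be
#' checked against exact bookkeeping.
#'
#' @param urban,non_urban [grid_series()] objects on a shared grid.
#' @param cfg A [synthetic_config()].
#' @return List: `records` (data.frame `station_id`, `network`, `lon`,
#'   `lat`, `cell_y`, `cell_x`, `bias`), `series` (data.frame
#'   `station_id`, `time`, `temperature_C`), `perturbations`
#'   (data.frame `station_id`, `time`, `eps` = bias + noise).
#' @export
gen_stations <- function(urban, non_urban, cfg) {
  validate_synthetic_config(cfg)
  if (!same_grid(urban$grid, non_urban$grid)) stop("scenario fields on different grids")
  grid <- urban$grid
  st <- cfg$stations
  cx <- (grid$nx + 1) / 2; cy <- (grid$ny + 1) / 2
  ix <- rep(seq_len(grid$nx), each = grid$ny)
  iy <- rep(seq_len(grid$ny), grid$nx)
  r <- sqrt((ix - cx)^2 + (iy - cy)^2)
  rmax <- max(r)
  edge <- which(r >= 0.7 * rmax)
  central <- which(r <= 0.45 * rmax)
  if (st$n_official > length(edge))
    stop("requested ", st$n_official, " official stations but only ",
         length(edge), " edge cells")
  if (st$n_pws > length(central))
    stop("requested ", st$n_pws, " PWS but only ", length(central), " central cells")

  set.seed(substream_seed(cfg$seed, "stations/placement"))
  cells <- c(sample(edge, st$n_official), sample(central, st$n_pws))
  network <- c(rep("official", st$n_official), rep("pws", st$n_pws))
  noise_sd <- c(rep(st$official_noise_sd, st$n_official), rep(st$pws_noise_sd, st$n_pws))
  bias_sd <- c(rep(st$official_bias_sd, st$n_official), rep(st$pws_bias_sd, st$n_pws))

  set.seed(substream_seed(cfg$seed, "stations/bias"))
  bias <- ifelse(bias_sd > 0, stats::rnorm(length(cells), 0, bias_sd), 0)

  nt <- length(urban$times)
  records <- data.frame(
    station_id = sprintf("%s_%02d", ifelse(network == "official", "OFF", "PWS"),
                         seq_along(cells)),
    network = network,
    lon = grid$x[ix[cells]], lat = grid$y[iy[cells]],
    cell_y = iy[cells], cell_x = ix[cells], bias = bias)

  set.seed(substream_seed(cfg$seed, "stations/noise"))
  series <- vector("list", length(cells))
  perts <- vector("list", length(cells))
  for (k in seq_along(cells)) {
    src <- urban$values[, iy[cells[k]], ix[cells[k]]]
    noise <- if (noise_sd[k] > 0) stats::rnorm(nt, 0, noise_sd[k]) else numeric(nt)
    eps <- bias[k] + noise
    series[[k]] <- data.frame(station_id = records$station_id[k],
                              time = urban$times, temperature_C = src + eps)
    perts[[k]] <- data.frame(station_id = records$station_id[k],
                             time = urban$times, eps = eps)
  }
  list(records = records,
       series = do.call(rbind, c(series, list(make.row.names = FALSE))),
       perturbations = do.call(rbind, c(perts, list(make.row.names = FALSE))))
}
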