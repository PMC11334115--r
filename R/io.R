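# Plain-text serialisation of every input the pipeline consumes. The
# gridded format is a CSV with a commented metadata header carrying the
# CF-style attributes that matter here (units, scenario, grid geometry);
# temperature may be stored in K or degC and is normalised to degC on
# read via the units attribute.

#' Write a gridded temperature series
#'
#' @param field A [grid_series()].
#' @param path Output path.
#' @param units `"K"` (default, CF-style export) or `"degC"`.
#' @export
write_gridded <- function(field, path, units = c("K", "degC")) {
  units <- match.arg(units)
  g <- field$grid
  hdr <- c("#uhimort_grid: 1",
           paste0("#scenario: ", field$scenario),
           paste0("#units: ", units),
           paste0("#lon0: ", format(g$x[1], digits = 15)),
           paste0("#lat0: ", format(g$y[1], digits = 15)),
           paste0("#nx: ", g$nx), paste0("#ny: ", g$ny),
           paste0("#dx: ", format(g$dx, digits = 15)),
           paste0("#dy: ", format(g$dy, digits = 15)))
  nt <- length(field$times)
  vals <- field$values
  if (units == "K") vals <- vals + 273.15
  df <- data.frame(
    time = format(rep(field$times, g$ny * g$nx), "%Y-%m-%dT%H:%M:%SZ"),
    y = rep(rep(seq_len(g$ny), each = nt), g$nx),
    x = rep(seq_len(g$nx), each = nt * g$ny),
    value = as.vector(vals))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gridded temperature series
#'
#' Validates the metadata header (a missing units attribute is an
#' error), converts kelvin to degC, and rejects NaN blocks and
#' non-monotone or irregular time axes.
#'
#' @param path Path written by [write_gridded()].
#' @return A [grid_series()] in degC.
#' @export
read_gridded <- function(path) {
  lines <- readLines(path)
  hdr_n <- sum(startsWith(lines, "#"))
  hdr <- lines[seq_len(hdr_n)]
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#", "", h)
    k <- sub(":.*$", "", kv)
    meta[[trimws(k)]] <- trimws(sub("^[^:]*:", "", kv))
  }
  if (is.null(meta$units)) stop("gridded file has no units attribute: ", path)
  if (!meta$units %in% c("K", "degC"))
    stop("unrecognised units '", meta$units, "' in ", path)
  df <- utils::read.csv(text = lines[-seq_len(hdr_n)])
  grid <- reg_grid(as.numeric(meta$lon0), as.numeric(meta$lat0),
                   nx = as.integer(meta$nx), ny = as.integer(meta$ny),
                   dx = as.numeric(meta$dx), dy = as.numeric(meta$dy))
  times <- sort(unique(as.POSIXct(df$time, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")))
  if (anyNA(times)) stop("corrupted time axis in ", path)
  dt <- diff(as.numeric(times))
  if (any(dt <= 0)) stop("non-monotone time axis in ", path)
  if (any(abs(dt - 3600) > 1e-6)) stop("irregular time step in ", path)
  nt <- length(times)
  if (nrow(df) != nt * grid$ny * grid$nx)
    stop("gridded file is not a complete time x y x cube: ", path)
  o <- order(df$x, df$y, match(as.POSIXct(df$time, format = "%Y-%m-%dT%H:%M:%SZ",
                                          tz = "UTC"), times))
  vals <- array(df$value[o], dim = c(nt, grid$ny, grid$nx))
  if (anyNA(vals)) stop("NaN block in gridded file: ", path)
  if (meta$units == "K") vals <- vals - 273.15
  grid_series(vals, times, grid,
              scenario = if (identical(meta$scenario, "non-urban")) "non-urban" else "urban")
}

#' Write / read population counts on a grid
#' @param pop A [population_grid()].
#' @param path File path.
#' @export
write_population <- function(pop, path) {
  g <- pop$grid
  hdr <- c("#uhimort_population: 1",
           paste0("#lon0: ", format(g$x[1], digits = 15)),
           paste0("#lat0: ", format(g$y[1], digits = 15)),
           paste0("#nx: ", g$nx), paste0("#ny: ", g$ny),
           paste0("#dx: ", format(g$dx, digits = 15)),
           paste0("#dy: ", format(g$dy, digits = 15)))
  df <- data.frame(y = rep(seq_len(g$ny), g$nx),
                   x = rep(seq_len(g$nx), each = g$ny),
                   count = as.vector(pop$counts))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  lines <- readLines(path)
  hdr_n <- sum(startsWith(lines, "#"))
  meta <- list()
  for (h in lines[seq_len(hdr_n)]) {
    kv <- sub("^#", "", h)
    meta[[trimws(sub(":.*$", "", kv))]] <- trimws(sub("^[^:]*:", "", kv))
  }
  df <- utils::read.csv(text = lines[-seq_len(hdr_n)])
  grid <- reg_grid(as.numeric(meta$lon0), as.numeric(meta$lat0),
                   nx = as.integer(meta$nx), ny = as.integer(meta$ny),
                   dx = as.numeric(meta$dx), dy = as.numeric(meta$dy))
  counts <- matrix(0, grid$ny, grid$nx)
  counts[cbind(df$y, df$x)] <- df$count
  population_grid(counts, grid)
}

#' Read / write a boundary polygon as GeoJSON
#'
#' Reads the outer ring of the first Polygon feature.
#'
#' @param path GeoJSON file path.
#' @return Two-column matrix of (lon, lat) vertices.
#' @export
read_boundary_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  geom <- if (identical(gj$type, "FeatureCollection")) gj$features[[1]]$geometry
          else if (identical(gj$type, "Feature")) gj$geometry else gj
  if (!identical(geom$type, "Polygon"))
    stop("boundary must be a GeoJSON Polygon, got ", geom$type)
  ring <- geom$coordinates[[1]]
  m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
  if (nrow(m) < 4L) stop("degenerate boundary ring")
  m
}

#' @rdname read_boundary_geojson
#' @param poly Two-column vertex matrix.
#' @export
write_boundary_geojson <- function(poly, path) {
  poly <- close_ring(poly)
  coords <- lapply(seq_len(nrow(poly)), function(i) c(poly[i, 1], poly[i, 2]))
  gj <- list(type = "Feature", properties = list(name = "region"),
             geometry = list(type = "Polygon", coordinates = list(coords)))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Mortality, pollutant and station CSV round trips
#'
#' Column layouts: mortality `(date, age_group, deaths)` with
#' `age_group` in `{0-64, 65-74, 75plus, all}`; pollutants
#' `(timestamp, pollutant, concentration_ugm3)`; stations
#' `(station_id, network, lat, lon, timestamp, temperature_C)`.
#'
#' @param mortality,path Arguments as named.
#' @export
write_mortality_csv <- function(mortality, path) {
  utils::write.csv(mortality[, c("date", "age_group", "deaths")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mortality_csv
#' @export
read_mortality_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c(date = "Date"))
  check_mortality(df)
  df
}

#' @rdname write_mortality_csv
#' @param pollution data.frame `time`, `pollutant`, `concentration_ugm3`.
#' @export
write_pollution_csv <- function(pollution, path) {
  out <- data.frame(timestamp = format(pollution$time, "%Y-%m-%dT%H:%M:%SZ"),
                    pollutant = pollution$pollutant,
                    concentration_ugm3 = pollution$concentration_ugm3)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mortality_csv
#' @export
read_pollution_csv <- function(path) {
  df <- utils::read.csv(path)
  data.frame(time = as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
             pollutant = df$pollutant,
             concentration_ugm3 = df$concentration_ugm3)
}

#' @rdname write_mortality_csv
#' @param stations List with `records` and `series` (see [gen_stations()]).
#' @export
write_stations_csv <- function(stations, path) {
  df <- merge(stations$series,
              stations$records[, c("station_id", "network", "lat", "lon")],
              by = "station_id")
  df <- df[order(df$station_id, df$time), ]
  out <- data.frame(station_id = df$station_id, network = df$network,
                    lat = df$lat, lon = df$lon,
                    timestamp = format(df$time, "%Y-%m-%dT%H:%M:%SZ"),
                    temperature_C = df$temperature_C)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mortality_csv
#' @export
read_stations_csv <- function(path) {
  df <- utils::read.csv(path)
  df$time <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  records <- unique(df[, c("station_id", "network", "lat", "lon")])
  rownames(records) <- NULL
  list(records = records,
       series = df[, c("station_id", "time", "temperature_C")])
}
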