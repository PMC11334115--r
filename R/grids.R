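#' Regular longitude/latitude grid
#'
#' Cell centres are equally spaced; cells are the rectangles of width
#' `dx` and height `dy` around each centre. Coordinates are degrees.
#'
#' @param lon0,lat0 Centre coordinates of the lower-left cell (degrees).
#' @param nx,ny Number of cells along longitude / latitude.
#' @param dx,dy Cell size in degrees.
#' @return An object of class `reg_grid` with fields `x`, `y` (cell-centre
#'   coordinate vectors), `dx`, `dy`, `nx`, `ny`.
#' @export
reg_grid <- function(lon0, lat0, nx, ny, dx, dy = dx) {
  if (nx < 1 || ny < 1) stop("degenerate grid: nx and ny must be >= 1")
  if (dx <= 0 || dy <= 0) stop("cell size must be positive")
  structure(
    list(x = lon0 + (seq_len(nx) - 1) * dx,
         y = lat0 + (seq_len(ny) - 1) * dy,
         dx = dx, dy = dy, nx = as.integer(nx), ny = as.integer(ny)),
    class = "reg_grid")
}

#' @export
print.reg_grid <- function(x, ...) {
  cat(sprintf("<reg_grid %dx%d cells, dx=%g dy=%g, lon [%g, %g], lat [%g, %g]>\n",
              x$ny, x$nx, x$dx, x$dy, min(x$x), max(x$x), min(x$y), max(x$y)))
  invisible(x)
}

# cell edge vectors (length n+1)
grid_x_edges <- function(grid) c(grid$x - grid$dx / 2, grid$x[grid$nx] + grid$dx / 2)
grid_y_edges <- function(grid) c(grid$y - grid$dy / 2, grid$y[grid$ny] + grid$dy / 2)

same_grid <- function(a, b, tol = 1e-9) {
  a$nx == b$nx && a$ny == b$ny &&
    max(abs(a$x - b$x)) < tol && max(abs(a$y - b$y)) < tol
}

#' Hourly gridded temperature field for one scenario
#'
#' @param values Numeric array with dim `(n_time, ny, nx)`, degrees Celsius.
#' @param times POSIXct vector of hourly timestamps (UTC).
#' @param grid A [reg_grid()].
#' @param scenario Scenario label, `"urban"` or `"non-urban"`.
#' @return An object of class `grid_series`.
#' @export
grid_series <- function(values, times, grid, scenario = c("urban", "non-urban")) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(grid, "reg_grid"))
  d <- dim(values)
  if (length(d) != 3L || d[1] != length(times) || d[2] != grid$ny || d[3] != grid$nx)
    stop("values must have dim (n_time, ny, nx) matching times and grid")
  assert_hourly(times, "grid_series")
  if (anyNA(values)) stop("grid_series: values contain NaN/NA")
  structure(list(values = values, times = times, grid = grid, scenario = scenario),
            class = "grid_series")
}

#' @export
print.grid_series <- function(x, ...) {
  cat(sprintf("<grid_series '%s': %d hours x %d x %d cells, %.1f to %.1f degC>\n",
              x$scenario, length(x$times), x$grid$ny, x$grid$nx,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Population counts on a regular grid
#'
#' Counts are persons per cell (an extensive quantity) on the same grid
#' as the temperature fields.
#'
#' @param counts Numeric matrix `(ny, nx)` of non-negative person counts.
#' @param grid A [reg_grid()].
#' @return An object of class `population_grid` with a `total` field.
#' @export
population_grid <- function(counts, grid) {
  stopifnot(inherits(grid, "reg_grid"))
  if (!all(dim(counts) == c(grid$ny, grid$nx)))
    stop("counts must be a (ny, nx) matrix matching the grid")
  if (any(counts < 0)) stop("population counts must be non-negative")
  structure(list(counts = counts, grid = grid, total = sum(counts)),
            class = "population_grid")
}

#' Time series of a regional exposure metric
#'
#' A thin data.frame wrapper: hourly series carry a `time` column
#' (POSIXct), daily series a `date` column (Date); both have `value`.
#'
#' @param df data.frame with `time` or `date` plus `value`.
#' @param metric One of `hourly_mean`, `daily_mean`, `lag012_mean`,
#'   `daily_max_8h_mean`, `daily_max`.
#' @param units `"degC"` or `"ugm3"`.
#' @param scenario Free-form label carried through the analysis.
#' @return data.frame of class `exposure_series` with attributes
#'   `metric`, `units`, `scenario`.
#' @export
exposure_series <- function(df, metric, units = "degC", scenario = "") {
  metric <- match.arg(metric, c("hourly_mean", "daily_mean", "lag012_mean",
                                "daily_max_8h_mean", "daily_max", "hourly_raw"))
  if (!"value" %in% names(df)) stop("exposure_series needs a 'value' column")
  if (!any(c("time", "date") %in% names(df)))
    stop("exposure_series needs a 'time' or 'date' column")
  if ("date" %in% names(df)) {
    if (anyDuplicated(df$date)) stop("daily exposure_series has duplicated days")
  }
  structure(df, metric = metric, units = units, scenario = scenario,
            class = c("exposure_series", "data.frame"))
}

#' @export
print.exposure_series <- function(x, ...) {
  cat(sprintf("<exposure_series %s [%s] scenario='%s', n=%d>\n",
              attr(x, "metric"), attr(x, "units"), attr(x, "scenario"), nrow(x)))
  print(utils::head(as.data.frame(x)))
  invisible(x)
}

es_metric <- function(x) attr(x, "metric")
es_units <- function(x) attr(x, "units")
es_scenario <- function(x) attr(x, "scenario")
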