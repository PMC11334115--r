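#' Conservative area-weighted regridding of population counts
#'
#' Population is an extensive quantity: each source count is split
#' across target cells in proportion to geometric overlap, so totals
#' are conserved whenever the target grid covers the sources.
#'
#' @param source Either a [population_grid()] (grid-to-grid regrid) or a
#'   list of features, each `list(coords = <2-col vertex matrix>,
#'   count = <persons>)` (polygon-to-grid regrid).
#' @param target A [reg_grid()].
#' @return A [population_grid()] on the target grid.
#' @export
regrid_conservative <- function(source, target) {
  stopifnot(inherits(target, "reg_grid"))
  tx <- grid_x_edges(target); ty <- grid_y_edges(target)

  if (inherits(source, "population_grid")) {
    sg <- source$grid
    sx <- grid_x_edges(sg); sy <- grid_y_edges(sg)
    fx <- overlap_fractions(sx, tx)            # (n_sx, n_tx)
    fy <- overlap_fractions(sy, ty)            # (n_sy, n_ty)
    if (sum(fx) == 0 || sum(fy) == 0)
      stop("source and target grids do not overlap")
    counts <- t(fy) %*% source$counts %*% fx   # (n_ty, n_tx)
    return(population_grid(counts, target))
  }

  if (!is.list(source) || !length(source))
    stop("source must be a population_grid or a non-empty feature list")
  counts <- matrix(0, target$ny, target$nx)
  any_overlap <- FALSE
  for (i in seq_along(source)) {
    f <- source[[i]]
    if (is.null(f$coords) || nrow(as.matrix(f$coords)) < 3L)
      stop("invalid geometry in source feature ", i)
    a <- abs(polygon_area(f$coords))
    if (a <= 0) stop("invalid geometry (zero area) in source feature ", i)
    # restrict the cell loop to the feature's bounding box
    bb <- apply(as.matrix(f$coords), 2, range)
    jx <- which(tx[-1] > bb[1, 1] & tx[-length(tx)] < bb[2, 1])
    jy <- which(ty[-1] > bb[1, 2] & ty[-length(ty)] < bb[2, 2])
    for (y in jy) for (x in jx) {
      ov <- rect_overlap_area(f$coords, tx[x], tx[x + 1], ty[y], ty[y + 1])
      if (ov > 0) {
        counts[y, x] <- counts[y, x] + f$count * ov / a
        any_overlap <- TRUE
      }
    }
  }
  if (!any_overlap) stop("source features do not overlap the target grid")
  population_grid(counts, target)
}

# fraction of each source interval [edges_s] covered by each target
# interval [edges_t]; rows = source cells, cols = target cells
overlap_fractions <- function(edges_s, edges_t) {
  ns <- length(edges_s) - 1L; nt <- length(edges_t) - 1L
  lo <- outer(edges_s[-length(edges_s)], edges_t[-length(edges_t)], pmax)
  hi <- outer(edges_s[-1], edges_t[-1], pmin)
  frac <- pmax(0, hi - lo) / rep(diff(edges_s), nt)
  matrix(frac, ns, nt)
}

#' Boolean region mask from a boundary polygon
#'
#' A cell belongs to the region iff its centre lies inside the polygon
#' (binary membership; no partial-cell weighting).
#'
#' @param boundary Two-column vertex matrix (lon, lat) of the region
#'   boundary ring.
#' @param grid A [reg_grid()].
#' @return Logical `(ny, nx)` matrix of class `region_mask`.
#' @export
make_region_mask <- function(boundary, grid) {
  stopifnot(inherits(grid, "reg_grid"))
  cx <- rep(grid$x, each = grid$ny)
  cy <- rep(grid$y, grid$nx)
  inside <- point_in_polygon(cx, cy, boundary)
  m <- matrix(inside, grid$ny, grid$nx)
  if (!any(m)) stop("boundary polygon contains no cell centre")
  structure(m, class = c("region_mask", class(m)))
}

#' Regional population-weighted temperature series
#'
#' @param field A [grid_series()].
#' @param pop A [population_grid()] on the same grid.
#' @param mask A [make_region_mask()] result (or any logical matrix);
#'   `NULL` means the whole grid.
#' @return An hourly [exposure_series()] in degC:
#'   `value(t) = sum_i w_i T_i(t) / sum_i w_i` over masked cells.
#' @export
population_weighted_series <- function(field, pop, mask = NULL) {
  stopifnot(inherits(field, "grid_series"), inherits(pop, "population_grid"))
  if (!same_grid(field$grid, pop$grid))
    stop("field and population are on different grids")
  if (is.null(mask)) mask <- matrix(TRUE, field$grid$ny, field$grid$nx)
  if (!all(dim(mask) == c(field$grid$ny, field$grid$nx)))
    stop("mask dimensions do not match the grid")
  w <- pop$counts[mask]
  if (sum(w) <= 0) stop("masked population is zero; cannot weight")
  nt <- length(field$times)
  flat <- matrix(field$values, nrow = nt)       # (nt, ny*nx), column-major
  vals <- as.vector(flat[, as.vector(mask), drop = FALSE] %*% w) / sum(w)
  exposure_series(data.frame(time = field$times, value = vals),
                  metric = "hourly_mean", units = "degC",
                  scenario = field$scenario)
}

#' Aggregate an hourly series to daily mean or maximum
#'
#' A day is kept only if at least 75% of its 24 hours are present
#' (>= 18 non-missing hours); dropped days are reported via `message()`.
#'
#' @param hourly An hourly [exposure_series()].
#' @param stat `"mean"` or `"max"`.
#' @param utc_offset Hours defining the local civil day boundary.
#' @param min_hours Completeness threshold (default 18).
#' @return A daily [exposure_series()].
#' @export
daily_aggregate <- function(hourly, stat = c("mean", "max"), utc_offset = 0,
                            min_hours = 18L) {
  stat <- match.arg(stat)
  if (!nrow(hourly)) stop("empty hourly series")
  dts <- local_date(hourly$time, utc_offset)
  ok <- !is.na(hourly$value)
  n_ok <- tapply(ok, dts, sum)
  f <- if (stat == "mean") function(v) mean(v, na.rm = TRUE) else function(v) max(v, na.rm = TRUE)
  agg <- tapply(hourly$value, dts, f)
  keep <- n_ok >= min_hours
  if (any(!keep))
    message("daily_aggregate: dropping ", sum(!keep), " incomplete day(s): ",
            paste(names(agg)[!keep], collapse = ", "))
  if (!any(keep)) stop("no day meets the completeness threshold")
  exposure_series(
    data.frame(date = as.Date(names(agg)[keep]), value = as.numeric(agg[keep])),
    metric = if (stat == "mean") "daily_mean" else "daily_max",
    units = es_units(hourly), scenario = es_scenario(hourly))
}

#' 0-2 day lag mean of a daily series
#'
#' `value(d) = mean(X_d, X_{d-1}, X_{d-2})`; the first two days of the
#' record have no complete lag window and are excluded. No partial
#' windows: a gap in the dates is an error, never silently diluted.
#'
#' @param daily A gap-free daily [exposure_series()].
#' @return A daily [exposure_series()] with metric `lag012_mean`.
#' @export
lag_mean <- function(daily) {
  if (nrow(daily) < 3L) stop("need at least 3 days for a 0-2 day lag mean")
  if (any(diff(as.integer(daily$date)) != 1L)) stop("daily series has gaps")
  v <- zoo::rollmeanr(daily$value, k = 3L)
  exposure_series(data.frame(date = daily$date[-(1:2)], value = v),
                  metric = "lag012_mean", units = es_units(daily),
                  scenario = es_scenario(daily))
}

#' Daily maximum 8-hour running mean
#'
#' For every hour the mean over the 8-hour window ending there is taken
#' (valid with >= 6 of 8 hours present; hours before the record start
#' count as missing); each window is attributed to the local day that
#' contains its ending hour, and a day is valid with >= 18 valid
#' windows. The daily value is the maximum valid window mean — the
#' standard ozone exposure metric.
#'
#' @param hourly An hourly concentration [exposure_series()] (ug/m3,
#'   values >= 0 or NA).
#' @param utc_offset Hours defining the local day boundary.
#' @param min_hours_per_window,min_windows_per_day Completeness rules.
#' @return A daily [exposure_series()] with metric `daily_max_8h_mean`.
#' @export
daily_max_8h_running_mean <- function(hourly, utc_offset = 0,
                                      min_hours_per_window = 6L,
                                      min_windows_per_day = 18L) {
  if (!nrow(hourly)) stop("empty hourly series")
  assert_hourly(hourly$time, "concentration series")
  if (any(hourly$value < 0, na.rm = TRUE)) stop("negative concentrations")
  v <- c(rep(NA_real_, 7L), hourly$value)
  n <- nrow(hourly)
  wmean <- vapply(seq_len(n), function(i) {
    w <- v[i:(i + 7L)]
    if (sum(!is.na(w)) >= min_hours_per_window) mean(w, na.rm = TRUE) else NA_real_
  }, numeric(1))
  dts <- local_date(hourly$time, utc_offset)
  nwin <- tapply(!is.na(wmean), dts, sum)
  dmax <- tapply(wmean, dts, function(w) if (all(is.na(w))) NA_real_ else max(w, na.rm = TRUE))
  keep <- nwin >= min_windows_per_day & !is.na(dmax)
  if (any(!keep))
    message("daily_max_8h_running_mean: dropping ", sum(!keep),
            " day(s) with too few valid windows: ",
            paste(names(dmax)[!keep], collapse = ", "))
  if (!any(keep)) stop("no day has enough valid 8-hour windows")
  exposure_series(
    data.frame(date = as.Date(names(dmax)[keep]), value = as.numeric(dmax[keep])),
    metric = "daily_max_8h_mean", units = es_units(hourly),
    scenario = es_scenario(hourly))
}

#' Urban-heat-island intensity summary
#'
#' UHII here is the urban-scenario minus counterfactual non-urban-
#' scenario difference, not an urban-minus-rural station difference.
#' Returns min/mean/max of the hourly population-weighted difference
#' plus per-cell time-mean difference maps for all hours, daytime
#' (08:00-20:00) and nighttime (20:00-08:00).
#'
#' @param urban,non_urban [grid_series()] on a shared grid and times.
#' @param pop A [population_grid()]; `NULL` weights uniformly.
#' @param mask Optional region mask.
#' @param utc_offset Hours; defines the day/night split.
#' @return List: `hourly` (data.frame `time`, `diff`), `min`, `mean`,
#'   `max`, and maps `map_all`, `map_day`, `map_night`.
#' @export
uhii_stats <- function(urban, non_urban, pop = NULL, mask = NULL, utc_offset = 0) {
  if (!same_grid(urban$grid, non_urban$grid)) stop("scenario grids differ")
  if (length(urban$times) != length(non_urban$times) ||
      any(abs(as.numeric(urban$times) - as.numeric(non_urban$times)) > 1e-6))
    stop("scenario time axes are misaligned")
  grid <- urban$grid
  if (is.null(pop))
    pop <- population_grid(matrix(1, grid$ny, grid$nx), grid)
  u <- population_weighted_series(urban, pop, mask)
  n <- population_weighted_series(non_urban, pop, mask)
  d <- u$value - n$value
  h <- ((as.numeric(urban$times) / 3600) %% 24 + utc_offset) %% 24
  day <- h >= 8 & h < 20
  dv <- urban$values - non_urban$values
  map_of <- function(sel) apply(dv[sel, , , drop = FALSE], c(2, 3), mean)
  list(hourly = data.frame(time = urban$times, diff = d),
       min = min(d), mean = mean(d), max = max(d),
       map_all = map_of(rep(TRUE, length(h))),
       map_day = map_of(day), map_night = map_of(!day))
}
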