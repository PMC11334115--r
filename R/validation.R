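#' Match a station to its nearest grid cell
#'
#' Nearest cell centre by great-circle (haversine) distance; ties are
#' broken deterministically toward the lowest `(y, x)` index.
#'
#' @param lon,lat Station coordinates (degrees).
#' @param grid A [reg_grid()].
#' @return List `y`, `x` (cell indices) and `dist_m`.
#' @export
match_station_to_cell <- function(lon, lat, grid) {
  xe <- grid_x_edges(grid); ye <- grid_y_edges(grid)
  if (lon < xe[1] || lon > xe[length(xe)] || lat < ye[1] || lat > ye[length(ye)])
    stop(sprintf("station (%.4f, %.4f) lies outside the grid bounds", lon, lat))
  cx <- rep(grid$x, each = grid$ny)
  cy <- rep(grid$y, grid$nx)
  d <- geosphere::distHaversine(c(lon, lat), cbind(cx, cy))
  # order candidates by (distance, y, x); tolerance absorbs fp ties
  best <- min(d)
  cand <- which(d <= best + 1e-6)
  iy <- (cand - 1L) %% grid$ny + 1L
  ix <- (cand - 1L) %/% grid$ny + 1L
  o <- order(iy, ix)[1]
  list(y = iy[o], x = ix[o], dist_m = d[cand[o]])
}

#' Per-station validation metrics
#'
#' Residuals are model minus observation on paired hours:
#' mean bias, MAE, RMSE, and temporal Pearson correlation. A constant
#' observation series leaves the correlation undefined; it is returned
#' as `NA` with `r_defined = FALSE`, never silently zero.
#'
#' @param obs,model Paired numeric vectors (same hours).
#' @param min_pairs Minimum paired non-missing hours (default 24).
#' @return List: `bias`, `mae`, `rmse`, `r`, `r_defined`, `n`.
#' @export
station_metrics <- function(obs, model, min_pairs = 24L) {
  if (length(obs) != length(model)) stop("obs and model lengths differ")
  ok <- !is.na(obs) & !is.na(model)
  if (sum(ok) < min_pairs)
    stop("only ", sum(ok), " paired hours; need >= ", min_pairs)
  o <- obs[ok]; m <- model[ok]
  res <- m - o
  r_def <- stats::sd(o) > 0 && stats::sd(m) > 0
  list(bias = mean(res), mae = mean(abs(res)), rmse = sqrt(mean(res^2)),
       r = if (r_def) stats::cor(o, m) else NA_real_,
       r_defined = r_def, n = sum(ok))
}

#' Validate a station set against a gridded scenario field
#'
#' Each station is matched to its nearest grid cell and compared to
#' that cell's series on paired timestamps. Stations with fewer than
#' `min_pairs` paired hours are excluded and reported.
#'
#' @param stations List as returned by [gen_stations()] or read from a
#'   station CSV: `records` (with `station_id`, `network`, `lon`,
#'   `lat`) and `series` (`station_id`, `time`, `temperature_C`).
#' @param field A [grid_series()].
#' @param min_pairs Completeness threshold.
#' @return data.frame of per-station metrics with `station_id`,
#'   `network`, `scenario`, `cell_y`, `cell_x`, `obs_mean`,
#'   `model_mean` and the [station_metrics()] columns.
#' @export
validate_stations <- function(stations, field, min_pairs = 24L) {
  recs <- stations$records
  out <- list()
  for (i in seq_len(nrow(recs))) {
    sid <- recs$station_id[i]
    cell <- match_station_to_cell(recs$lon[i], recs$lat[i], field$grid)
    ser <- stations$series[stations$series$station_id == sid, ]
    idx <- match(as.numeric(ser$time), as.numeric(field$times))
    paired <- !is.na(idx)
    obs <- ser$temperature_C[paired]
    mod <- field$values[cbind(idx[paired], cell$y, cell$x)]
    n_ok <- sum(!is.na(obs) & !is.na(mod))
    if (n_ok < min_pairs) {
      message("validate_stations: excluding ", sid, " (", n_ok, " paired hours)")
      next
    }
    met <- station_metrics(obs, mod, min_pairs)
    out[[sid]] <- data.frame(
      station_id = sid, network = recs$network[i], scenario = field$scenario,
      cell_y = cell$y, cell_x = cell$x,
      bias = met$bias, mae = met$mae, rmse = met$rmse,
      r = met$r, r_defined = met$r_defined, n = met$n,
      obs_mean = mean(obs, na.rm = TRUE), model_mean = mean(mod, na.rm = TRUE))
  }
  if (!length(out)) stop("no station passed the completeness threshold")
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Network-level validation summary
#'
#' Unweighted mean of the per-station metrics within each network x
#' scenario group, plus the spatial Pearson correlation between
#' station time-means and matched-cell time-means (how well the model
#' reproduces the spatial pattern of mean temperature).
#'
#' @param per_station Output of [validate_stations()] (one or more
#'   scenarios row-bound).
#' @return data.frame with one row per network x scenario: `n_stations`,
#'   mean `bias`, `mae`, `rmse`, mean temporal `r` (over stations where
#'   defined), and `spatial_r` (`NA` if fewer than 3 stations or zero
#'   variance).
#' @export
network_summary <- function(per_station) {
  groups <- unique(per_station[, c("network", "scenario")])
  if (!nrow(groups)) stop("empty validation input")
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- per_station[per_station$network == groups$network[i] &
                       per_station$scenario == groups$scenario[i], ]
    sp_r <- if (nrow(g) >= 3 && stats::sd(g$obs_mean) > 0 && stats::sd(g$model_mean) > 0)
      stats::cor(g$obs_mean, g$model_mean) else NA_real_
    data.frame(network = groups$network[i], scenario = groups$scenario[i],
               n_stations = nrow(g),
               bias = mean(g$bias), mae = mean(g$mae), rmse = mean(g$rmse),
               r = mean(g$r[g$r_defined], na.rm = TRUE),
               spatial_r = sp_r)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
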