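# Independent brute-force oracles. Each re-derives the quantity under
# test from first principles with plain loops, sharing no code with the
# implementation.

# small, fast study configuration for tests
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(grid_shape = c(6L, 6L), n_days = 8L, heatwave_peak_day = 5L,
                   population = list(total = 1e5, profile = "gaussian",
                                     length_scale = 2),
                   stations = list(n_official = 3L, n_pws = 5L,
                                   official_noise_sd = 0.5, pws_noise_sd = 2.0,
                                   official_bias_sd = 0, pws_bias_sd = 1.0),
                   seed = 1L)
  do.call(synthetic_config, utils::modifyList(defaults, args))
}

# single-loop attributable-deaths oracle: exposure vector x, deaths
# matrix m (days x strata), named beta vector, threshold
brute_attribution <- function(x, m, beta, threshold) {
  total <- 0
  for (d in seq_along(x)) {
    for (a in seq_len(ncol(m))) {
      rr <- exp(beta[[a]] * max(0, x[d] - threshold))
      total <- total + (rr - 1) / rr * m[d, a]
    }
  }
  total
}

# pollutant oracle: concentrations C, all-ages deaths m, percent per 10
brute_pollutant <- function(conc, m, pct) {
  total <- 0
  for (d in seq_along(conc)) {
    rr <- (1 + pct / 100)^(conc[d] / 10)
    total <- total + (rr - 1) / rr * m[d]
  }
  total
}

# exhaustive daily-max-8h-running-mean oracle on a complete hourly
# series (no missing values): all windows of 8 consecutive hours whose
# ending hour lies in the day
brute_max_8h <- function(times, values, utc_offset = 0) {
  dts <- as.Date(times + utc_offset * 3600, tz = "UTC")
  days <- sort(unique(dts))
  out <- numeric(length(days))
  for (k in seq_along(days)) {
    idx <- which(dts == days[k])
    best <- -Inf
    nwin <- 0
    for (i in idx) {
      lo <- i - 7L
      w <- values[max(1L, lo):i]
      n_absent <- if (lo < 1L) 1L - lo else 0L
      if (8L - n_absent >= 6L) {
        best <- max(best, mean(w))
        nwin <- nwin + 1L
      }
    }
    out[k] <- if (nwin >= 18L) best else NA_real_
  }
  data.frame(date = days, value = out)
}

# haversine distance, written out from the formula
brute_haversine <- function(lon1, lat1, lon2, lat2, r = 6378137) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# conservative regrid oracle: explicit rectangle-intersection loop
brute_regrid <- function(src_counts, sxe, sye, txe, tye) {
  nty <- length(tye) - 1L; ntx <- length(txe) - 1L
  out <- matrix(0, nty, ntx)
  for (sy in seq_len(nrow(src_counts))) for (sx in seq_len(ncol(src_counts))) {
    a_src <- (sxe[sx + 1] - sxe[sx]) * (sye[sy + 1] - sye[sy])
    for (ty in seq_len(nty)) for (tx in seq_len(ntx)) {
      ox <- max(0, min(sxe[sx + 1], txe[tx + 1]) - max(sxe[sx], txe[tx]))
      oy <- max(0, min(sye[sy + 1], tye[ty + 1]) - max(sye[sy], tye[ty]))
      out[ty, tx] <- out[ty, tx] + src_counts[sy, sx] * ox * oy / a_src
    }
  }
  out
}

# daily exposure series constructed directly
make_daily_series <- function(values, start = as.Date("2022-07-01"),
                              metric = "lag012_mean", scenario = "test") {
  exposure_series(data.frame(date = start + seq_along(values) - 1,
                             value = values),
                  metric = metric, units = "degC", scenario = scenario)
}

make_hourly_series <- function(values, start = as.POSIXct("2022-07-01 00:00:00", tz = "UTC"),
                               units = "degC", scenario = "test") {
  exposure_series(data.frame(time = start + 3600 * (seq_along(values) - 1),
                             value = values),
                  metric = "hourly_mean", units = units, scenario = scenario)
}

# mortality data.frame from a days x strata matrix
make_mortality <- function(m, start = as.Date("2022-07-01"),
                           strata = paste0("s", seq_len(ncol(m)))) {
  do.call(rbind, lapply(seq_len(ncol(m)), function(a)
    data.frame(date = start + seq_len(nrow(m)) - 1,
               age_group = strata[a], deaths = m[, a])))
}
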