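test_that("identity regrid returns its input and conserves totals", {
  g <- reg_grid(0, 50, nx = 4, ny = 3, dx = 0.1)
  set.seed(42)
  pop <- population_grid(matrix(runif(12, 0, 1000), 3, 4), g)
  out <- regrid_conservative(pop, g)
  expect_equal(out$counts, pop$counts, tolerance = 1e-12)
  expect_equal(out$total, pop$total, tolerance = 1e-12)
})

test_that("a polygon split exactly in half lands 500/500", {
  # two target cells side by side; source square centred on the join
  tg <- reg_grid(0.05, 0.05, nx = 2, ny = 1, dx = 0.1)
  sq <- rbind(c(0.06, 0.02), c(0.14, 0.02), c(0.14, 0.08), c(0.06, 0.08))
  out <- regrid_conservative(list(list(coords = sq, count = 1000)), tg)
  expect_equal(as.numeric(out$counts), c(500, 500), tolerance = 1e-9)
})

test_that("random grid-to-grid regrid matches the geometric oracle and conserves population", {
  for (seed in 1:5) {
    set.seed(seed)
    src <- reg_grid(0, 0, nx = 5, ny = 5, dx = 0.1)
    # target covers the source entirely
    tgt <- reg_grid(-0.1, -0.1, nx = 3, ny = 3, dx = 0.25)
    counts <- matrix(runif(25, 0, 500), 5, 5)
    pop <- population_grid(counts, src)
    out <- regrid_conservative(pop, tgt)
    oracle <- brute_regrid(counts,
                           c(src$x - src$dx / 2, src$x[5] + src$dx / 2),
                           c(src$y - src$dy / 2, src$y[5] + src$dy / 2),
                           c(tgt$x - tgt$dx / 2, tgt$x[3] + tgt$dx / 2),
                           c(tgt$y - tgt$dy / 2, tgt$y[3] + tgt$dy / 2))
    expect_equal(out$counts, oracle, tolerance = 1e-12)
    expect_equal(out$total, sum(counts), tolerance = 1e-9 * sum(counts))
  }
})

test_that("polygon-to-grid regrid agrees with rectangle interval arithmetic", {
  tgt <- reg_grid(0.5, 0.5, nx = 4, ny = 4, dx = 1)
  # an axis-aligned rectangle whose overlap with each cell is computable
  # by interval arithmetic alone
  rect <- rbind(c(0.3, 0.7), c(2.9, 0.7), c(2.9, 3.1), c(0.3, 3.1))
  out <- regrid_conservative(list(list(coords = rect, count = 260)), tgt)
  xe <- c(tgt$x - 0.5, 4); ye <- c(tgt$y - 0.5, 4)
  a_tot <- (2.9 - 0.3) * (3.1 - 0.7)
  oracle <- matrix(0, 4, 4)
  for (y in 1:4) for (x in 1:4) {
    ox <- max(0, min(2.9, xe[x + 1]) - max(0.3, xe[x]))
    oy <- max(0, min(3.1, ye[y + 1]) - max(0.7, ye[y]))
    oracle[y, x] <- 260 * ox * oy / a_tot
  }
  expect_equal(out$counts, oracle, tolerance = 1e-12)
  expect_equal(out$total, 260, tolerance = 1e-9 * 260)
})

test_that("non-overlapping domains and invalid geometries fail loudly", {
  tgt <- reg_grid(0, 0, nx = 2, ny = 2, dx = 0.1)
  far <- reg_grid(10, 10, nx = 2, ny = 2, dx = 0.1)
  pop <- population_grid(matrix(1, 2, 2), far)
  expect_error(regrid_conservative(pop, tgt), "overlap")
  bad <- list(list(coords = rbind(c(0, 0), c(1, 1)), count = 10))
  expect_error(regrid_conservative(bad, tgt), "invalid geometry in source feature 1")
})

test_that("region mask is cell-centre point-in-polygon, cross-checked against mgcv", {
  skip_if_not_installed("mgcv")
  g <- reg_grid(0.5, 0.5, nx = 4, ny = 4, dx = 1)
  lshape <- rbind(c(0.2, 0.2), c(3.6, 0.2), c(3.6, 1.7), c(1.8, 1.7),
                  c(1.8, 3.8), c(0.2, 3.8))
  m <- make_region_mask(lshape, g)
  cx <- rep(g$x, each = g$ny); cy <- rep(g$y, g$nx)
  oracle <- matrix(mgcv::in.out(rbind(lshape, lshape[1, ]), cbind(cx, cy)),
                   g$ny, g$nx)
  expect_identical(unclass(m)[, ], oracle)

  whole <- rbind(c(-1, -1), c(6, -1), c(6, 6), c(-1, 6))
  expect_true(all(make_region_mask(whole, g)))
  nothing <- rbind(c(10, 10), c(11, 10), c(11, 11), c(10, 11))
  expect_error(make_region_mask(nothing, g), "no cell centre")
})

test_that("population weighting reduces to the plain mean, a single cell, and the hand-computed sum", {
  g <- reg_grid(0, 50, nx = 3, ny = 3, dx = 0.1)
  times <- as.POSIXct("2022-07-01 00:00", tz = "UTC") + 3600 * 0:47
  set.seed(1)
  vals <- array(rnorm(48 * 9, 20, 3), dim = c(48, 3, 3))
  fld <- grid_series(vals, times, g, "urban")

  uni <- population_grid(matrix(5, 3, 3), g)
  expect_equal(population_weighted_series(fld, uni)$value,
               apply(vals, 1, mean), tolerance = 1e-12)

  one <- matrix(0, 3, 3); one[2, 3] <- 100
  pw1 <- population_weighted_series(fld, population_grid(one, g))
  expect_equal(pw1$value, vals[, 2, 3], tolerance = 1e-12)

  set.seed(2)
  w <- matrix(runif(9, 1, 10), 3, 3)
  pw <- population_weighted_series(fld, population_grid(w, g))
  manual <- vapply(1:48, function(t) sum(w * vals[t, , ]) / sum(w), numeric(1))
  expect_equal(pw$value, manual, tolerance = 1e-12)

  # weighted mean bounded by the field range at every timestamp
  expect_true(all(pw$value >= apply(vals, 1, min) - 1e-12))
  expect_true(all(pw$value <= apply(vals, 1, max) + 1e-12))

  expect_error(population_weighted_series(fld, population_grid(matrix(0, 3, 3), g)),
               "zero")
})

test_that("daily aggregation handles constants, arithmetic, completeness and a brute oracle", {
  h24 <- make_hourly_series(rep(20, 48))
  expect_true(all(daily_aggregate(h24, "mean")$value == 20))
  expect_true(all(daily_aggregate(h24, "max")$value == 20))

  oneday <- make_hourly_series(1:24)
  expect_equal(daily_aggregate(oneday, "mean", min_hours = 24)$value, 12.5)
  expect_equal(daily_aggregate(oneday, "max", min_hours = 24)$value, 24)

  set.seed(3)
  v <- rnorm(240, 22, 4)
  h <- make_hourly_series(v)
  agg <- daily_aggregate(h, "mean")
  oracle <- vapply(0:9, function(d) mean(v[d * 24 + 1:24]), numeric(1))
  expect_equal(agg$value, oracle, tolerance = 1e-12)

  # knock out 8 hours of day 2: below the 75% completeness rule
  v2 <- v; v2[25:32] <- NA
  expect_message(agg2 <- daily_aggregate(make_hourly_series(v2), "mean"),
                 "dropping 1 incomplete")
  expect_equal(nrow(agg2), 9L)
  expect_error(daily_aggregate(make_hourly_series(numeric(0))), "empty")
})

test_that("lag mean drops the warm-up days and matches a rolling oracle", {
  const <- make_daily_series(rep(18, 6), metric = "daily_mean")
  lm1 <- lag_mean(const)
  expect_equal(nrow(lm1), 4L)
  expect_true(all(lm1$value == 18))

  three <- make_daily_series(c(20, 22, 24), metric = "daily_mean")
  expect_equal(lag_mean(three)$value, 22)

  set.seed(4)
  v <- rnorm(30, 20, 5)
  lm <- lag_mean(make_daily_series(v, metric = "daily_mean"))
  oracle <- vapply(3:30, function(d) mean(v[(d - 2):d]), numeric(1))
  expect_equal(lm$value, oracle, tolerance = 1e-12)

  # linear-in-time series: lag mean is the series shifted one day's slope
  lin <- make_daily_series(5 + 0.7 * (1:10), metric = "daily_mean")
  ll <- lag_mean(lin)
  expect_equal(ll$value, lin$value[3:10] - 0.7, tolerance = 1e-12)

  expect_error(lag_mean(make_daily_series(c(1, 2), metric = "daily_mean")), "3 days")
  gap <- make_daily_series(1:5, metric = "daily_mean")
  gap$date[4] <- gap$date[4] + 5
  expect_error(lag_mean(gap), "gaps")
})

test_that("daily max 8h running mean: constants, spike arithmetic, exhaustive oracle, ordering", {
  const <- make_hourly_series(rep(50, 72), units = "ugm3")
  expect_true(all(daily_max_8h_running_mean(const)$value == 50))

  # one 80 ug/m3 hour in an otherwise-zero record: best window mean 80/8
  v <- rep(0, 72); v[36] <- 80
  spike <- daily_max_8h_running_mean(make_hourly_series(v, units = "ugm3"))
  expect_equal(spike$value[2], 10)

  set.seed(5)
  vr <- runif(120, 0, 100)
  got <- daily_max_8h_running_mean(make_hourly_series(vr, units = "ugm3"))
  times <- as.POSIXct("2022-07-01 00:00", tz = "UTC") + 3600 * (seq_along(vr) - 1)
  oracle <- brute_max_8h(times, vr)
  oracle <- oracle[!is.na(oracle$value), ]
  expect_equal(as.data.frame(got)$value, oracle$value, tolerance = 1e-12)
  expect_equal(got$date, oracle$date)

  # >= daily mean of the same series, equality only for a constant day
  dm <- daily_aggregate(make_hourly_series(vr, units = "ugm3"), "mean")
  paired <- merge(as.data.frame(got), as.data.frame(dm), by = "date")
  expect_true(all(paired$value.x >= paired$value.y - 1e-12))
  expect_true(all(paired$value.x > paired$value.y))

  expect_error(daily_max_8h_running_mean(make_hourly_series(c(-1, rep(1, 30)),
                                                            units = "ugm3")),
               "negative")
})

test_that("uhii_stats: identity, constant offset, and recomputation from raw arrays", {
  cfg <- tiny_config(noise_sd = 0)
  f <- gen_temperature_grids(cfg)
  pop <- gen_population_grid(cfg)

  same <- uhii_stats(f$urban, f$urban, pop)
  expect_equal(c(same$min, same$mean, same$max), c(0, 0, 0))

  shifted <- f$urban
  shifted$values <- f$non_urban$values + 2
  off <- uhii_stats(shifted, f$non_urban, pop)
  expect_equal(c(off$min, off$mean, off$max), c(2, 2, 2), tolerance = 1e-12)

  s <- uhii_stats(f$urban, f$non_urban, pop)
  w <- pop$counts / sum(pop$counts)
  d <- vapply(seq_along(f$urban$times), function(t)
    sum(w * (f$urban$values[t, , ] - f$non_urban$values[t, , ])), numeric(1))
  expect_equal(s$mean, mean(d), tolerance = 1e-12)
  expect_equal(s$min, min(d), tolerance = 1e-12)
  expect_equal(s$max, max(d), tolerance = 1e-12)

  # day map vs night map at the centre
  cy <- ceiling(f$urban$grid$ny / 2); cx <- ceiling(f$urban$grid$nx / 2)
  expect_gt(s$map_night[cy, cx], s$map_day[cy, cx])

  # misaligned time axes rejected
  g2 <- f$non_urban
  g2$times <- g2$times + 3600
  expect_error(uhii_stats(f$urban, g2, pop), "misaligned")
})

test_that("exposure operators are invariant to cell storage order", {
  g <- reg_grid(0, 50, nx = 3, ny = 2, dx = 0.1)
  times <- as.POSIXct("2022-07-01 00:00", tz = "UTC") + 3600 * 0:25
  set.seed(6)
  vals <- array(rnorm(26 * 6, 20, 2), dim = c(26, 2, 3))
  w <- matrix(runif(6, 1, 5), 2, 3)
  fld <- grid_series(vals, times, g, "urban")
  base <- population_weighted_series(fld, population_grid(w, g))$value
  # permute the (y, x) layout consistently: weighted mean must not move
  perm_vals <- vals[, , 3:1, drop = FALSE]
  perm_w <- w[, 3:1]
  permuted <- population_weighted_series(grid_series(perm_vals, times, g, "urban"),
                                         population_grid(perm_w, g))$value
  expect_equal(base, permuted, tolerance = 1e-12)
})
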