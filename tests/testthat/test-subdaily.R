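# One year of hourly data with growth at chosen clock hours each day. A
# warm-up reading on Dec 31 of the previous year absorbs the zero-growth
# initialization of the first observation.
year_hourly_growth <- function(growth_hours, gro = 1, year = 2021, days = 1:365) {
  ts <- seq(as.POSIXct(sprintf("%d-12-31 23:00", year - 1), tz = "UTC"),
            as.POSIXct(sprintf("%d-12-31 23:00", year), tz = "UTC"), by = "hour")
  lt <- as.POSIXlt(ts)
  inc <- ifelse(lt$hour %in% growth_hours & (lt$yday + 1) %in% days, gro, 0)
  partition_zero_growth(data.frame(timestamp = ts, diameter = 100 + cumsum(inc)))
}

test_that("diel profile isolates the growing hours", {
  p <- year_hourly_growth(3)
  pr <- diel_profile(p, 2021)
  expect_equal(pr$probability[pr$hour == 3], 100)
  expect_equal(pr$contribution[pr$hour == 3], 100)
  expect_equal(pr$probability[pr$hour != 3], rep(0, 23))
  expect_equal(pr$contribution[pr$hour != 3], rep(0, 23))
  expect_equal(pr$rate[pr$hour == 3], 1)
  expect_true(all(is.na(pr$rate[pr$hour != 3])))

  pr_u <- diel_profile(year_hourly_growth(0:23), 2021)
  expect_equal(pr_u$contribution, rep(100 / 24, 24))
})

test_that("contributions sum to 100 and the weighted identity recovers annual GRO", {
  set.seed(71)
  for (rep in 1:5) {
    ts <- seq(as.POSIXct("2021-01-01", tz = "UTC"),
              as.POSIXct("2021-12-31 23:00", tz = "UTC"), by = "hour")
    d <- 300 + cumsum(rnorm(length(ts), 0.02, 0.6))
    p <- partition_zero_growth(data.frame(timestamp = ts, diameter = d))
    pr <- diel_profile(p, 2021)
    expect_equal(sum(pr$contribution), 100, tolerance = 1e-12)
    rate <- ifelse(is.na(pr$rate), 0, pr$rate)
    recovered <- sum(pr$probability / 100 * pr$n_obs * rate)
    expect_equal(recovered, annual_growth(p, 2021))
    # uniform rescaling leaves probability/contribution unchanged, scales rate
    p2 <- partition_zero_growth(data.frame(timestamp = ts, diameter = 2 * d))
    pr2 <- diel_profile(p2, 2021)
    expect_equal(pr2$probability, pr$probability)
    expect_equal(pr2$contribution, pr$contribution)
    expect_equal(pr2$rate, 2 * pr$rate)
  }
})

test_that("median trend takes per-hour medians across profiles", {
  p <- year_hourly_growth(5)
  pr <- diel_profile(p, 2021)
  expect_equal(median_trend(pr)$probability, pr$probability)

  three <- do.call(rbind, lapply(c(1, 5, 9), function(v) {
    data.frame(tree_id = paste0("t", v), year = 2021, hour = 0:23, n_obs = 100,
               probability = v, rate = v, contribution = 100 / 24)
  }))
  expect_equal(median_trend(three)$probability, rep(5, 24))

  set.seed(72)
  rand <- do.call(rbind, lapply(1:7, function(i) {
    data.frame(tree_id = i, year = 2021, hour = 0:23, n_obs = 100,
               probability = runif(24, 0, 100), rate = rexp(24),
               contribution = runif(24))
  }))
  mt <- median_trend(rand)
  for (h in c(0, 7, 23)) {
    expect_equal(mt$probability[mt$hour == h],
                 oracle_median(rand$probability[rand$hour == h]))
  }
})

test_that("night/day windows have 11 and 13 hour labels with the stated ratios", {
  expect_length(night_hours(), 11)
  expect_length(day_hours(), 13)
  expect_setequal(c(night_hours(), day_hours()), 0:23)

  flat <- data.frame(hour = 0:23, probability = 10, rate = 1, contribution = 100 / 24)
  nd <- night_day_summary(flat)
  expect_equal(nd$ratio, rep(1, 3))

  nocturnal <- transform(flat, probability = ifelse(hour %in% night_hours(), 10, 0))
  nd2 <- night_day_summary(nocturnal)
  expect_false(is.finite(nd2$ratio[nd2$measure == "probability"]))
})

test_that("midnight-zeroed diel curve finds extremes and counts shrink hours", {
  # sinusoid with maximum at hour 10, identical every day
  ts <- seq(as.POSIXct("2021-06-01", tz = "UTC"),
            as.POSIXct("2021-06-30 23:00", tz = "UTC"), by = "hour")
  hr <- as.POSIXlt(ts)$hour
  d <- 100 + 5 * sin(2 * pi * (hr - 4) / 24)
  p <- partition_zero_growth(data.frame(timestamp = ts, diameter = d))
  dd <- diel_delta_d(p, "all")
  expect_equal(dd$first_max_hour, 10)
  # closed form: the hourly curve declines between consecutive hours h, h+1
  # where sin(2*pi*(h+1-4)/24) < sin(2*pi*(h-4)/24)
  curve <- 5 * sin(2 * pi * ((0:23) - 4) / 24)
  expect_equal(dd$shrink_hours, sum(diff(curve) < 0))
  expect_equal(dd$min_hour, which.min(curve[11:24]) + 9)

  # monotone increasing day
  p2 <- year_hourly_growth(0:23, gro = 0.5)
  dd2 <- diel_delta_d(p2, "all")
  expect_equal(dd2$shrink_hours, 0)
  expect_false(dd2$intermittent)
})

test_that("growing-day filter keeps only days with positive daily growth", {
  p <- year_hourly_growth(3, days = 100:150)
  dd_all <- diel_delta_d(p, "all")
  dd_gro <- diel_delta_d(p, "growing")
  expect_equal(dd_gro$n_days, 51)
  expect_gt(dd_all$n_days, dd_gro$n_days)
  # on growing days the curve steps by the growth increment at hour 3
  expect_equal(dd_gro$curve$mean_delta_d[dd_gro$curve$hour >= 3],
               rep(1, 21))
})

test_that("night-only generator grows only in the night window", {
  cfg <- synthetic_config(years = 1, night_only = TRUE)
  cl <- simulate_climate(cfg, seed = 3)
  sim <- simulate_stem(cl, cfg, seed = 3)
  p <- partition_zero_growth(sim$series)
  pr <- diel_profile(p, 2001)
  expect_equal(pr$contribution[pr$hour %in% day_hours()], rep(0, 13))
  nd <- night_day_summary(pr)
  expect_true(nd$ratio[nd$measure == "contribution"] >= 10)
})

test_that("shrink hours and night:day contribution ratio are rank-correlated across sets", {
  pars <- list(c(1, 16), c(3, 10), c(5, 8), c(8, 6), c(10, 4))
  res <- t(sapply(pars, function(kk) {
    cfg <- synthetic_config(years = 1, uniform_hours = TRUE, k_t = kk[1],
                            k_r = kk[2], g_max = 0.4, annual_target = 4000)
    cl <- simulate_climate(cfg, seed = 11)
    sim <- simulate_stem(cl, cfg, seed = 11)
    p <- partition_zero_growth(sim$series)
    nd <- night_day_summary(diel_profile(p, 2001))
    c(shrink = diel_delta_d(p, "all")$shrink_hours,
      ratio = nd$ratio[nd$measure == "contribution"])
  }))
  expect_gt(cor(res[, "shrink"], res[, "ratio"], method = "spearman"), 0)
})

test_that("hourly growth surfaces respond only to the driving predictor", {
  set.seed(73)
  ts <- seq(as.POSIXct("2021-01-01", tz = "UTC"),
            as.POSIXct("2021-03-31 23:00", tz = "UTC"), by = "hour")
  n <- length(ts)
  clim <- data.frame(timestamp = ts, vpd = runif(n, 0, 2), rew = runif(n))
  # growth linear in rew only, no noise
  inc <- 0.5 * clim$rew
  part <- partition_zero_growth(data.frame(timestamp = ts, diameter = 100 + cumsum(inc)))
  part <- part[-1, ]   # drop the zero-growth initialization row: gro is then
                       # exactly linear in rew everywhere
  s <- hourly_gro_surfaces(part, clim, pairs = "vpd_rew", grid_res = 8,
                           max_points = Inf)$vpd_rew
  g <- s$grid[s$grid$inside_hull, ]
  # along each rew row, predictions are flat in vpd
  for (r in unique(g$rew)) {
    row <- g$prediction[g$rew == r]
    if (length(row) > 1) expect_lt(max(row) - min(row), 1e-6)
  }

  # all-zero growth gives an all-zero surface
  part0 <- part; part0$gro <- 0
  expect_error(hourly_gro_surfaces(part0, clim, pairs = "vpd_rew"), NA)
  s0 <- hourly_gro_surfaces(part0, clim, pairs = "vpd_rew", grid_res = 6,
                            max_points = 5000)$vpd_rew
  expect_true(all(is.na(s0$grid$prediction) |
                    abs(s0$grid$prediction) < 1e-12))
})
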