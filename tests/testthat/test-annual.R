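# Builds a year of hourly data with growth placed on chosen days: one growth
# hour (at noon) per listed DOY with the given increment.
year_with_growth <- function(gro_by_doy, year = 2021) {
  ts <- seq(as.POSIXct(sprintf("%d-01-01", year), tz = "UTC"),
            as.POSIXct(sprintf("%d-12-31 23:00", year), tz = "UTC"), by = "hour")
  doy <- as.POSIXlt(ts)$yday + 1
  hr <- as.POSIXlt(ts)$hour
  inc <- numeric(length(ts))
  if (nrow(gro_by_doy) > 0) {
    i <- match(paste(gro_by_doy$doy, 12), paste(doy, hr))
    inc[i] <- gro_by_doy$gro
  }
  data.frame(timestamp = ts, diameter = 100 + cumsum(inc))
}

test_that("annual growth sums the year's increments", {
  s <- year_with_growth(data.frame(doy = c(100, 150, 200), gro = c(2, 0, 2)))
  p <- partition_zero_growth(s)
  expect_equal(annual_growth(p, 2021), 4)
  cnt <- growth_duration_counts(p, 2021)
  expect_equal(cnt$gro_hours, 2)
  expect_equal(cnt$gro_days, 2)
})

test_that("phenology thresholds follow the end-of-day >= convention", {
  # 1 um/day uniformly over DOY 100..199
  s <- year_with_growth(data.frame(doy = 100:199, gro = 1))
  p <- partition_zero_growth(s)
  phen <- growth_phenology(p, 2021)
  expect_equal(phen$gro_start, 104)
  expect_equal(phen$gro_end, 194)
  expect_equal(phen$gro_length, 90)

  # point mass: all growth on DOY 150
  s <- year_with_growth(data.frame(doy = 150, gro = 5))
  phen <- growth_phenology(partition_zero_growth(s), 2021)
  expect_equal(phen$gro_start, 150)
  expect_equal(phen$gro_end, 150)
  expect_equal(phen$gro_length, 0)

  # zero growth: undefined, flagged
  s <- year_with_growth(data.frame(doy = integer(), gro = numeric()))
  expect_warning(phen <- growth_phenology(partition_zero_growth(s), 2021),
                 "undefined")
  expect_true(is.na(phen$gro_start))
})

test_that("growing days within the season define the TWD duration percentage", {
  # growth every day of a 100-day season, never any shrinkage
  s <- year_with_growth(data.frame(doy = 100:199, gro = 1))
  p <- partition_zero_growth(s)
  phen <- growth_phenology(p, 2021)
  tw <- twd_summaries(p, 2021, phen)
  expect_equal(tw$twd_max, 0)
  expect_equal(tw$twd_cum, 0)
  expect_equal(tw$twd_gro_length_pct, 0)

  # 25 growing days inside a season spanning 100 days
  doys <- c(100, seq(104, 192, by = 4), 199)
  s <- year_with_growth(data.frame(doy = doys, gro = 1))
  p <- partition_zero_growth(s)
  phen <- list(gro_start = 100L, gro_end = 199L, gro_length = 99L)
  tw <- twd_summaries(p, 2021, phen)
  expect_equal(length(doys), 25)
  expect_equal(tw$twd_gro_length_pct, 75)
})

test_that("TWD summaries match a brute-force per-day classification", {
  set.seed(9)
  for (rep in 1:5) {
    ts <- seq(as.POSIXct("2021-01-01", tz = "UTC"),
              as.POSIXct("2021-12-31 23:00", tz = "UTC"), by = "hour")
    d <- 500 + cumsum(rnorm(length(ts), 0.02, 0.8))
    p <- partition_zero_growth(data.frame(timestamp = ts, diameter = d))
    phen <- growth_phenology(p, 2021)
    tw <- twd_summaries(p, 2021, phen)
    expect_equal(tw$twd_max, max(p$twd))
    expect_equal(tw$twd_cum, sum(p$twd))
    doy <- as.POSIXlt(p$timestamp)$yday + 1
    season <- doy >= phen$gro_start & doy <= phen$gro_end
    growing_days <- unique(doy[season & p$gro > 0])
    expected <- 100 * (1 - length(growing_days) /
                         (phen$gro_end - phen$gro_start + 1))
    expect_equal(tw$twd_gro_length_pct, max(0, min(100, expected)))
  }
})

test_that("climate cumulatives equal brute-force masked sums", {
  dates <- seq(as.Date("2021-01-01"), as.Date("2021-12-31"), by = "day")
  daily <- data.frame(date = dates, vpd_daily = rep(1, length(dates)),
                      rew_daily = rep(0.5, length(dates)))
  cc <- climate_cumulatives(daily, 2021, c(100, 199))
  expect_equal(cc$rew_cum_season, 50)
  expect_equal(cc$vpd_cum_season, 100)
  expect_equal(cc$vpd_cum_year, 365)

  set.seed(11)
  daily$vpd_daily <- rexp(nrow(daily))
  daily$rew_daily <- runif(nrow(daily))
  win <- c(80, 250)
  cc <- climate_cumulatives(daily, 2021, win)
  doy <- as.integer(format(dates, "%j"))
  expect_equal(cc$vpd_cum_season, sum(daily$vpd_daily[doy >= 80 & doy <= 250]))
  expect_equal(cc$rew_cum_year, sum(daily$rew_daily))

  expect_error(climate_cumulatives(daily, 2021, c(200, 100)), "configuration error")
  expect_error(climate_cumulatives(daily, 2019, c(80, 250)), "configuration error")
})

test_that("scaling diameters scales micrometre metrics and fixes counts and dates", {
  set.seed(21)
  ts <- seq(as.POSIXct("2021-01-01", tz = "UTC"),
            as.POSIXct("2021-12-31 23:00", tz = "UTC"), by = "hour")
  d <- 500 + cumsum(rnorm(length(ts), 0.02, 0.5))
  k <- 3.7
  m1 <- annual_metrics(partition_zero_growth(data.frame(timestamp = ts, diameter = d)), 2021)
  m2 <- annual_metrics(partition_zero_growth(data.frame(timestamp = ts, diameter = k * d)), 2021)
  expect_equal(m2$annual_gro, k * m1$annual_gro)
  expect_equal(m2$twd_max, k * m1$twd_max)
  expect_equal(m2$twd_cum, k * m1$twd_cum)
  for (col in c("gro_start", "gro_end", "gro_length", "gro_days", "gro_hours",
                "twd_gro_length_pct")) {
    expect_equal(m2[[col]], m1[[col]], label = col)
  }
})

test_that("annual metrics recover generator truth on a strict noise-free year", {
  cfg <- synthetic_config(years = 1)
  cl <- simulate_climate(cfg, seed = 4)
  sim <- simulate_stem(cl, cfg, seed = 4)
  p <- partition_zero_growth(sim$series)
  m <- annual_metrics(p, 2001)
  tr <- sim$truth_annual
  expect_equal(m$annual_gro, tr$annual_gro, tolerance = 1e-9)
  expect_identical(m$gro_hours, tr$gro_hours)
  expect_identical(m$gro_days, tr$gro_days)
  expect_equal(m$gro_start, tr$gro_start)
  expect_equal(m$gro_end, tr$gro_end)
  expect_equal(m$twd_max, tr$twd_max_true, tolerance = 1e-6)
})

test_that("measurement-set medians pool kept tree-years", {
  metrics <- data.frame(
    tree_id = c("a", "a", "b"), year = c(1, 2, 1),
    species = "sp", site_id = "s",
    gro_start = c(100, 110, 120), gro_end = c(200, 210, 260))
  s <- measurement_set_summary(metrics)
  expect_equal(s$median_gro_start, 110)
  expect_equal(s$median_gro_end, 210)
  expect_equal(s$n_trees, 2)
})
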