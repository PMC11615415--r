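test_that("climate tables read back sorted with duplicates rejected", {
  ts <- as.POSIXct("2020-03-01 00:00:00", tz = "UTC") + 3600 * (0:2)
  df <- data.frame(timestamp = format(ts, "%Y-%m-%d %H:%M:%S"),
                   t_air = c(10, 11, 12), rh_air = c(90, 85, 80))
  path <- write_temp_csv(df)
  got <- read_climate_table(path)
  expect_equal(nrow(got), 3)
  expect_equal(got$t_air, c(10, 11, 12))
  expect_s3_class(got$timestamp, "POSIXct")

  shuffled <- write_temp_csv(df[c(3, 1, 2), ])
  expect_equal(read_climate_table(shuffled), got, ignore_attr = TRUE)

  dup <- write_temp_csv(df[c(1, 1, 2), ])
  expect_error(read_climate_table(dup), "2020-03-01 00:00:00")

  bad <- write_temp_csv(transform(df, timestamp = c(df$timestamp[1:2], "not-a-time")))
  expect_error(read_climate_table(bad), "format error")

  expect_error(read_climate_table(path, column_map = c(t_air = "TA")),
               "configuration error")
})

test_that("column mapping and TSV dialect are honoured", {
  ts <- as.POSIXct("2020-03-01 00:00:00", tz = "UTC") + 3600 * (0:1)
  df <- data.frame(TIMESTAMP = format(ts, "%Y-%m-%dT%H:%M:%S"), TA = c(5, 6))
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", row.names = FALSE)
  got <- read_climate_table(path, column_map = c(timestamp = "TIMESTAMP", t_air = "TA"))
  expect_equal(got$t_air, c(5, 6))
})

test_that("hourly aggregation means states, sums rain, and flags empty hours", {
  ts <- as.POSIXct("2020-06-01 00:00:00", tz = "UTC") + 900 * (0:7)
  rec <- data.frame(timestamp = ts,
                    t_air = c(10, 10, 10, 10, NA, NA, NA, NA),
                    rain = c(1, 0, 0, 1, NA, NA, NA, NA))
  h <- aggregate_to_hourly(rec)
  expect_equal(h$t_air, c(10, NA))
  expect_equal(h$rain, c(2, NA))

  rec2 <- rec
  rec2$timestamp[2] <- rec2$timestamp[2] + 300
  expect_error(aggregate_to_hourly(rec2), "resolution error")
})

test_that("hourly aggregation matches a brute-force group-by and conserves rain mass", {
  set.seed(42)
  ts <- as.POSIXct("2020-06-01 00:00:00", tz = "UTC") + 900 * (0:(48 * 4 - 1))
  rec <- data.frame(timestamp = ts,
                    t_air = rnorm(length(ts), 15, 5),
                    rh_air = runif(length(ts), 30, 100),
                    swc = runif(length(ts), 10, 40),
                    rain = rpois(length(ts), 0.2) * runif(length(ts), 0, 3))
  h <- aggregate_to_hourly(rec)
  key <- format(rec$timestamp, "%Y-%m-%d %H")
  for (i in seq_len(nrow(h))) {
    rows <- rec[key == format(h$timestamp[i], "%Y-%m-%d %H"), ]
    expect_equal(h$t_air[i], mean(rows$t_air))
    expect_equal(h$rain[i], sum(rows$rain))
  }
  expect_equal(sum(h$rain), sum(rec$rain))
})

test_that("Tetens VPD matches the closed form and is monotone in humidity", {
  expect_equal(compute_vpd(25, 100), 0)
  for (t in c(-5, 0, 12, 30)) expect_equal(compute_vpd(t, 100), 0)
  # frozen from the closed form 0.6108*exp(17.27*T/(T+237.3))*(1-rh/100)
  expect_equal(compute_vpd(20, 50), 1.169141, tolerance = 1e-6)
  expect_equal(compute_vpd(0, 0), 0.6108, tolerance = 1e-9)
  rh <- seq(0, 100, by = 5)
  v <- compute_vpd(rep(18, length(rh)), rh)
  expect_true(all(diff(v) < 0))
  expect_equal(v[length(v)], 0)
  expect_equal(compute_vpd(15, 100.4), 0)    # overshoot clamped
  expect_error(compute_vpd(15, 101), "validation error")
  expect_error(compute_vpd(15, -1), "validation error")
})

test_that("REW rescales linearly between site extremes and clamps outside", {
  cal <- site_calibration("mesic", swc_min = 12, swc_max = 61)
  expect_equal(as.numeric(compute_rew(12, cal)), 0)
  expect_equal(as.numeric(compute_rew(61, cal)), 1)
  expect_equal(as.numeric(compute_rew(36.5, cal)), 0.5)
  # affine property off the endpoints
  a <- runif(20, 12, 61); b <- runif(20, 12, 61)
  expect_equal(as.numeric(compute_rew(a, cal)) - as.numeric(compute_rew(b, cal)),
               (a - b) / 49)
  out <- compute_rew(c(5, 70, 30), cal)
  expect_equal(attr(out, "n_clamped"), 2)
  expect_true(all(out >= 0 & out <= 1))
  expect_true(is.na(compute_rew(NA, cal)[1]))
  expect_error(site_calibration("x", 61, 12), "exceed")
})

test_that("daily climate medians equal the sort-and-middle oracle", {
  ts <- as.POSIXct("2020-04-01 00:00:00", tz = "UTC") + 3600 * (0:23)
  h <- data.frame(timestamp = ts, vpd = rep(1, 24), rew = 1:24 / 24)
  d <- daily_climate_summary(h)
  expect_equal(d$vpd_daily, 1)
  h2 <- data.frame(timestamp = ts, vpd = 1:24, rew = rep(0.5, 24))
  expect_equal(daily_climate_summary(h2)$vpd_daily, 12.5)

  set.seed(7)
  n_days <- 1000
  ts <- as.POSIXct("2015-01-01 00:00:00", tz = "UTC") + 3600 * (0:(24 * n_days - 1))
  h3 <- data.frame(timestamp = ts, vpd = rexp(length(ts)), rew = runif(length(ts)))
  h3$vpd[sample(length(ts), 2000)] <- NA
  d3 <- daily_climate_summary(h3)
  day <- as.Date(ts, tz = "UTC")
  expect_equal(d3$vpd_daily, as.numeric(tapply(h3$vpd, day, oracle_median)),
               ignore_attr = TRUE)
  expect_equal(d3$rew_daily, as.numeric(tapply(h3$rew, day, oracle_median)),
               ignore_attr = TRUE)
  # each daily value lies within the day's hourly range
  lo <- tapply(h3$rew, day, min); hi <- tapply(h3$rew, day, max)
  expect_true(all(d3$rew_daily >= lo & d3$rew_daily <= hi))
})
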