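# Coupled synthetic climate + stem generator. The stem model is a hydraulic
# capacitor: an elastic water pool is depleted by transpiration (VPD-driven,
# during daylight hours) and refilled from the soil (REW-driven); diameter =
# initial + cumulative growth - current depletion. In strict mode growth is
# only applied while the pool is full (depletion == 0), which makes the
# zero-growth partition recover the generator's truth exactly -- the exact
# oracle used throughout the tests. Relaxed mode allows turgor-limited growth
# at small depletion to probe the method's bias.

#' Configuration for the synthetic climate and stem generator
#'
#' Returns the default scenario (a Mediterranean site: winter-skewed rain,
#' hot dry summer, bimodal growing season) with any field overridden via
#' `...`. Units: temperatures degrees C, rain mm, diameters/pools
#' micrometres, rates per hour.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A validated list of class `synthetic_config`.
#' @section Fields:
#' Site: `years` (2), `mat` (mean annual temperature, 13), `seasonal_amp`
#' (9), `diel_amp` (4), `ar_phi`/`ar_sd` (temperature AR(1) noise, 0.8/1.2),
#' `annual_rain` (450), `rain_event_rate` (events per day, 0.35),
#' `bucket_capacity` (120 mm), `et_coef` (0.08 mm per kPa h),
#' `swc_min_pct`/`swc_max_pct` (8/40, bucket-to-SWC mapping).
#' Stem: `d0` (150000), `g_max` (2 micrometres per hour), `annual_target`
#' (3000 micrometres per year), `spring_window` (DOY 70--184),
#' `autumn_window` (DOY 245--320), `autumn_fraction` (0.25), `night_only`
#' (FALSE), `uniform_hours` (FALSE; TRUE disables every diel gate so growth
#' is hour-uniform), `rew_threshold` (0.15), `k_t` (shrink gain, 4
#' micrometres per kPa h), `k_r` (refill gain, 8 micrometres per h),
#' `w_max` (elastic pool capacity, 400 micrometres: depletion saturates once
#' the elastic tissue reaches its residual water content),
#' `transpiration_hours` (8--20), `strict_zero_growth` (TRUE), `relax_scale`
#' (50), `noise_sd` (0), `quantize` (FALSE).
#' @export
synthetic_config <- function(...) {
  cfg <- list(
    years = 2L, mat = 13, seasonal_amp = 9, diel_amp = 4,
    ar_phi = 0.8, ar_sd = 1.2,
    annual_rain = 420, rain_event_rate = 0.35,
    bucket_capacity = 100, et_coef = 0.25,
    swc_min_pct = 8, swc_max_pct = 40,
    d0 = 150000, g_max = 2, annual_target = 2000,
    spring_window = c(70L, 184L), autumn_window = c(245L, 320L),
    autumn_fraction = 0.25, night_only = FALSE, uniform_hours = FALSE,
    rew_threshold = 0.15, k_t = 4, k_r = 8, w_max = 400,
    transpiration_hours = 8L:20L,
    strict_zero_growth = TRUE, relax_scale = 50,
    noise_sd = 0, quantize = FALSE
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) {
    stop("configuration error: unknown field(s) ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(ov)] <- ov
  with(cfg, {
    stopifnot(years >= 1, g_max >= 0, k_t >= 0, k_r >= 0, et_coef >= 0,
              annual_rain >= 0, rain_event_rate >= 0,
              autumn_fraction >= 0, autumn_fraction <= 1,
              noise_sd >= 0, bucket_capacity > 0)
    if (spring_window[1] >= spring_window[2] || autumn_window[1] >= autumn_window[2] ||
        spring_window[2] >= autumn_window[1]) {
      stop("configuration error: phenology windows must be increasing and non-overlapping",
           call. = FALSE)
    }
  })
  structure(cfg, class = c("synthetic_config", "list"))
}

#' Simulate hourly site climate
#'
#' Temperature is an annual plus diel sinusoid with AR(1) noise; relative
#' humidity is anti-correlated with temperature (clamped to [5, 100]); rain
#' falls as winter-skewed marked Poisson events; soil water follows a bucket
#' that gains rainfall and loses water proportionally to VPD times REW. VPD
#' and REW are then derived with the package's climate operations (the
#' bucket-to-SWC mapping supplies the site calibration). Bit-identical under
#' a fixed `(cfg, seed)`.
#'
#' @param cfg A [synthetic_config()].
#' @param seed Integer seed.
#' @param start_year First calendar year (default 2001).
#' @return Hourly climate data.frame (`timestamp`, `t_air`, `rh_air`, `swc`,
#'   `rain`, `vpd`, `rew`).
#' @export
simulate_climate <- function(cfg = synthetic_config(), seed = 1L,
                             start_year = 2001L) {
  set.seed(seed)
  ts <- seq(
    from = as.POSIXct(sprintf("%d-01-01 00:00:00", start_year), tz = "UTC"),
    to = as.POSIXct(sprintf("%d-12-31 23:00:00", start_year + cfg$years - 1L), tz = "UTC"),
    by = "hour"
  )
  n <- length(ts)
  doy <- dp_doy(ts); hr <- dp_hour(ts)
  t_air <- cfg$mat +
    cfg$seasonal_amp * cos(2 * pi * (doy - 196) / 365.25) +
    cfg$diel_amp * sin(2 * pi * (hr - 9) / 24) +
    as.numeric(stats::arima.sim(list(ar = cfg$ar_phi), n,
                                sd = cfg$ar_sd * sqrt(1 - cfg$ar_phi^2)))
  rh_air <- dp_clamp(98 - 2.8 * (t_air - cfg$mat + 4) + stats::rnorm(n, 0, 2), 5, 100)

  # winter-skewed marked Poisson rain assigned to random hours
  rain <- numeric(n)
  if (cfg$annual_rain > 0 && cfg$rain_event_rate > 0) {
    dates <- unique(dp_date(ts))
    ddoy <- as.integer(format(dates, "%j"))
    rate <- cfg$rain_event_rate * (1 + 0.9 * cos(2 * pi * (ddoy - 15) / 365.25))
    n_ev <- stats::rpois(length(dates), rate)
    mean_amount <- cfg$annual_rain / (sum(rate) / cfg$years)
    if (sum(n_ev) > 0) {
      ev_day <- rep(seq_along(dates), n_ev)
      ev_hour <- sample(0:23, sum(n_ev), replace = TRUE)
      ev_amt <- stats::rgamma(sum(n_ev), shape = 0.8, scale = mean_amount / 0.8)
      idx <- match(as.numeric(as.POSIXct(dates[ev_day], tz = "UTC")) + 3600 * ev_hour,
                   as.numeric(ts))
      for (i in seq_along(idx)) rain[idx[i]] <- rain[idx[i]] + ev_amt[i]
    }
  }

  vpd <- compute_vpd(t_air, rh_air)
  S <- numeric(n)
  s <- 0.7 * cfg$bucket_capacity
  for (t in seq_len(n)) {
    s <- s + rain[t] - cfg$et_coef * vpd[t] * (s / cfg$bucket_capacity)
    s <- min(max(s, 0), cfg$bucket_capacity)
    S[t] <- s
  }
  swc <- cfg$swc_min_pct + (cfg$swc_max_pct - cfg$swc_min_pct) * S / cfg$bucket_capacity
  out <- data.frame(timestamp = ts, t_air = t_air, rh_air = rh_air,
                    swc = swc, rain = rain)
  derive_climate(out, site_calibration("synthetic", cfg$swc_min_pct, cfg$swc_max_pct))
}

#' Simulate a dendrometer series with an exact truth ledger
#'
#' Runs the hydraulic-capacitor stem model over a simulated climate. Each
#' hour the elastic depletion `W` gains `k_t * VPD` during transpiration
#' hours and loses `k_r * REW` (refill), floored at 0; growth is then drawn
#' against the seasonal budget when the hour is eligible (phenology window,
#' `REW > rew_threshold`, night gate if `night_only`) and -- in strict mode
#' -- only while `W == 0`. Annual growth is budgeted as
#' `(1 - autumn_fraction)` in the spring window and `autumn_fraction` in the
#' autumn window so the realized bimodal split is known. Observed diameter is
#' `d0 + cumulative growth - W`, plus optional Gaussian noise and 1-micron
#' quantization.
#'
#' @param climate Output of [simulate_climate()] covering the run.
#' @param cfg A [synthetic_config()].
#' @param seed Integer seed (observation noise only).
#' @param tree_id Label for the output series.
#' @return List with `series` (tree_id, timestamp, diameter), `truth`
#'   (per-hour `true_gro`, `depletion`, plus the noise-free diameter) and
#'   `truth_annual` (per-year totals, growing hours/days, 5%/95% phenology
#'   of the true cumulative curve, transition DOY at maximum depletion, and
#'   realized autumn fraction).
#' @export
simulate_stem <- function(climate, cfg = synthetic_config(), seed = 1L,
                          tree_id = "T1") {
  set.seed(seed)
  n <- nrow(climate)
  doy <- dp_doy(climate$timestamp)
  hr <- dp_hour(climate$timestamp)
  yr <- dp_year(climate$timestamp)
  in_spring <- doy >= cfg$spring_window[1] & doy <= cfg$spring_window[2]
  in_autumn <- doy >= cfg$autumn_window[1] & doy <= cfg$autumn_window[2]
  hour_ok <- if (cfg$uniform_hours) rep(TRUE, n)
    else if (cfg$night_only) hr %in% night_hours()
    else rep(TRUE, n)
  transp <- hr %in% cfg$transpiration_hours
  rew_ok <- climate$rew > cfg$rew_threshold

  g <- numeric(n); W <- numeric(n)
  w <- 0
  b_spring <- b_autumn <- 0
  cur_year <- -1L
  for (t in seq_len(n)) {
    if (yr[t] != cur_year) {
      cur_year <- yr[t]
      b_spring <- (1 - cfg$autumn_fraction) * cfg$annual_target
      b_autumn <- cfg$autumn_fraction * cfg$annual_target
    }
    if (transp[t]) w <- min(cfg$w_max, w + cfg$k_t * climate$vpd[t])
    w <- max(0, w - cfg$k_r * climate$rew[t])
    eligible <- hour_ok[t] && rew_ok[t] && (in_spring[t] || in_autumn[t])
    if (eligible) {
      pot <- if (cfg$strict_zero_growth) {
        if (w == 0) cfg$g_max else 0
      } else {
        cfg$g_max * exp(-w / cfg$relax_scale)
      }
      if (pot > 0) {
        if (in_spring[t]) {
          gt <- min(pot, b_spring); b_spring <- b_spring - gt
        } else {
          gt <- min(pot, b_autumn); b_autumn <- b_autumn - gt
        }
        g[t] <- gt
      }
    }
    W[t] <- w
  }

  d_true <- cfg$d0 + cumsum(g) - W
  d_obs <- d_true
  if (cfg$noise_sd > 0) d_obs <- d_obs + stats::rnorm(n, 0, cfg$noise_sd)
  if (cfg$quantize) d_obs <- round(d_obs)

  truth <- data.frame(timestamp = climate$timestamp, true_gro = g,
                      depletion = W, diameter_true = d_true)
  truth_annual <- do.call(rbind, lapply(unique(yr), function(y) {
    i <- yr == y
    gi <- g[i]; di <- doy[i]
    day_g <- tapply(gi, di, sum)
    cumd <- cumsum(day_g)
    total <- sum(gi)
    day_w <- tapply(W[i], di, max)
    transition <- as.integer(names(day_w))[which.max(day_w)]
    data.frame(
      tree_id = tree_id, year = y, annual_gro = total,
      gro_hours = sum(gi > 0), gro_days = length(unique(di[gi > 0])),
      gro_start = if (total > 0) as.integer(names(cumd))[which(cumd >= 0.05 * total)[1]] else NA_integer_,
      gro_end = if (total > 0) as.integer(names(cumd))[which(cumd >= 0.95 * total)[1]] else NA_integer_,
      transition_doy = transition,
      autumn_fraction = if (total > 0) sum(gi[di > transition]) / total else NA_real_,
      twd_max_true = max(W[i]),
      stringsAsFactors = FALSE
    )
  }))
  list(
    series = data.frame(tree_id = tree_id, timestamp = climate$timestamp,
                        diameter = d_obs, stringsAsFactors = FALSE),
    truth = truth,
    truth_annual = truth_annual
  )
}

#' Inject gap and flat artefacts into a dendrometer series
#'
#' Corrupts a series with the two artefact classes the annual QC gate
#' screens for: temporal gaps (rows removed) and frozen sensor values
#' (readings held constant). Specs must not overlap.
#'
#' @param series DendroSeries data.frame (`timestamp`, `diameter`).
#' @param specs Data.frame with columns `year`, `start_doy`, `length_days`,
#'   `type` (`"gap"` or `"flat"`).
#' @return List with `series` (corrupted) and `ledger` (the specs plus
#'   realized start/end timestamps and run hours).
#' @export
inject_artifacts <- function(series, specs) {
  stopifnot(all(c("year", "start_doy", "length_days", "type") %in% names(specs)))
  if (!all(specs$type %in% c("gap", "flat"))) {
    stop("configuration error: artefact type must be 'gap' or 'flat'", call. = FALSE)
  }
  specs$start <- as.POSIXct(sprintf("%d-01-01", specs$year), tz = "UTC") +
    (specs$start_doy - 1) * 86400
  specs$end <- specs$start + specs$length_days * 86400
  if (nrow(specs) > 1) {
    o <- order(specs$start)
    s <- specs[o, ]
    if (any(s$start[-1] < s$end[-nrow(s)])) {
      stop("configuration error: overlapping artefact specs", call. = FALSE)
    }
  }
  out <- series
  drop <- rep(FALSE, nrow(out))
  for (i in seq_len(nrow(specs))) {
    hit <- out$timestamp >= specs$start[i] & out$timestamp < specs$end[i]
    if (specs$type[i] == "gap") {
      drop <- drop | hit
    } else {
      out$diameter[hit] <- out$diameter[which(hit)[1]]
    }
    specs$run_hours[i] <- sum(hit)
  }
  list(series = out[!drop, , drop = FALSE], ledger = specs)
}
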