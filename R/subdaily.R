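# Hour-of-day decomposition of growth and shrinkage. Hour label = clock hour
# of the interval start; night window {21..23, 0..7} (11 h), day {8..20}
# (13 h), local standard time with no daylight-saving shifts.

#' Hour sets for the diel windows
#'
#' Night is 21:00--7:00 (11 clock-hour labels), day 8:00--20:00 (13 labels),
#' both inclusive.
#' @return Integer vector of clock hours.
#' @name diel_windows
NULL

#' @rdname diel_windows
#' @export
night_hours <- function() c(21L, 22L, 23L, 0L:7L)

#' @rdname diel_windows
#' @export
day_hours <- function() 8L:20L

#' Hourly growth probability, rate and contribution for one tree-year
#'
#' For each clock hour h: probability is the percentage of observed hours at
#' h with positive growth; rate is the mean growth over growing hours at h
#' (micrometres per hour, conditional on growth; `NA` where no growing hour
#' was observed); contribution is the growth summed at h as a percentage of
#' the annual total (defined only when annual growth is positive).
#'
#' @param part Partitioned series from [partition_zero_growth()].
#' @param year Calendar year.
#' @param tree_id Label carried into the output.
#' @return Data.frame with 24 rows: `tree_id`, `year`, `hour`, `n_obs`,
#'   `probability`, `rate`, `contribution`.
#' @export
diel_profile <- function(part, year, tree_id = part$tree_id[1] %||% NA_character_) {
  in_year <- dp_year(part$timestamp) == year
  hr <- dp_hour(part$timestamp[in_year])
  gro <- part$gro[in_year]
  total <- sum(gro)
  grp <- factor(hr, levels = 0:23)
  n_obs <- as.integer(table(grp))
  n_grow <- as.integer(tapply(gro > 0, grp, sum, default = 0L))
  sum_gro <- as.numeric(tapply(gro, grp, sum, default = 0))
  sum_gro[is.na(sum_gro)] <- 0
  rate <- ifelse(n_grow > 0, sum_gro / n_grow, NA_real_)
  data.frame(
    tree_id = tree_id, year = year, hour = 0:23, n_obs = n_obs,
    probability = ifelse(n_obs > 0, 100 * n_grow / n_obs, NA_real_),
    rate = rate,
    contribution = if (total > 0) 100 * sum_gro / total else NA_real_
  )
}

#' Median diel trend across tree-year profiles
#'
#' Per-hour median of probability, rate and contribution over a set of
#' [diel_profile()] results (the measurement-set trend).
#'
#' @param profiles Data.frame of stacked [diel_profile()] rows.
#' @return Data.frame with 24 rows: `hour`, `probability`, `rate`,
#'   `contribution`.
#' @export
median_trend <- function(profiles) {
  grp <- factor(profiles$hour, levels = 0:23)
  med <- function(x) as.numeric(tapply(x, grp, function(v) {
    if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE)
  }))
  data.frame(hour = 0:23, probability = med(profiles$probability),
             rate = med(profiles$rate), contribution = med(profiles$contribution))
}

#' Night/day averages and nighttime-to-daytime ratios
#'
#' Arithmetic means of probability, rate and contribution over the night
#' (21:00--7:00, 11 hour labels) and day (8:00--20:00, 13 labels) windows,
#' plus their night:day ratios. A ratio with zero day mean is `Inf` when the
#' night mean is positive (nocturnal-only behaviour) and `NA` when both
#' means vanish.
#'
#' @param profile A 24-row diel profile ([diel_profile()] or
#'   [median_trend()]).
#' @param night,day Integer hour sets (defaults per the diel windows).
#' @return Data.frame with one row per measure (`probability`, `rate`,
#'   `contribution`): `night_mean`, `day_mean`, `ratio`.
#' @export
night_day_summary <- function(profile, night = night_hours(), day = day_hours()) {
  stopifnot(all(0:23 %in% profile$hour))
  one <- function(measure) {
    v <- profile[[measure]][match(0:23, profile$hour)]
    nm <- mean(v[(0:23) %in% night], na.rm = TRUE)
    dm <- mean(v[(0:23) %in% day], na.rm = TRUE)
    ratio <- if (is.na(dm) || is.na(nm)) NA_real_
      else if (dm > 0) nm / dm
      else if (nm > 0) Inf
      else NA_real_
    data.frame(measure = measure, night_mean = nm, day_mean = dm, ratio = ratio,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(c("probability", "rate", "contribution"), one))
}

#' Mean diel stem-diameter course zeroed at midnight
#'
#' For each selected day, the hourly diameter deviation from the day's hour-0
#' reading; the mean over days gives the characteristic diel shrink-swell
#' curve. `shrink_hours` counts the hours where the mean curve declines
#' (`mean_delta_d[h+1] < mean_delta_d[h]`). When the curve is simple (one
#' rising phase, one shrinking phase, optional recovery) the first maximum
#' and the subsequent minimum hours are reported; otherwise the pattern is
#' flagged intermittent and those labels are `NA`.
#'
#' @param part Partitioned series from [partition_zero_growth()] (supplies
#'   both the diameter and the growing-day classification).
#' @param day_filter `"all"` days or `"growing"` days only (days with at
#'   least one growing hour).
#' @return List with `curve` (data.frame `hour`, `mean_delta_d`, `n_days`),
#'   `shrink_hours`, `first_max_hour`, `min_hour`, `intermittent`, `n_days`.
#' @export
diel_delta_d <- function(part, day_filter = c("all", "growing")) {
  day_filter <- match.arg(day_filter)
  d <- dp_date(part$timestamp)
  hr <- dp_hour(part$timestamp)
  keep_days <- unique(d)
  if (day_filter == "growing") {
    growing <- tapply(part$gro > 0, d, any)
    keep_days <- as.Date(names(growing))[growing]
  }
  sel <- d %in% keep_days
  if (!any(sel)) {
    return(list(curve = data.frame(hour = 0:23, mean_delta_d = NA_real_, n_days = 0L),
                shrink_hours = NA_integer_, first_max_hour = NA_integer_,
                min_hour = NA_integer_, intermittent = NA, n_days = 0L))
  }
  dd <- d[sel]; hh <- hr[sel]; dia <- part$diameter[sel]
  # anchor: the day's hour-0 reading; days missing hour 0 are skipped
  anchors <- dia[hh == 0][match(dd, dd[hh == 0])]
  ok <- !is.na(anchors)
  delta <- dia[ok] - anchors[ok]
  grp <- factor(hh[ok], levels = 0:23)
  curve <- data.frame(
    hour = 0:23,
    mean_delta_d = as.numeric(tapply(delta, grp, mean)),
    n_days = as.integer(table(grp))
  )
  m <- curve$mean_delta_d
  slopes <- diff(m)
  shrink_hours <- sum(slopes < 0, na.rm = TRUE)
  sgn <- sign(slopes[!is.na(slopes) & slopes != 0])
  runs <- if (length(sgn)) rle(sgn)$values else numeric(0)
  # simple diel course: rise, fall, optional rise (<= 3 sign phases,
  # starting upward)
  intermittent <- !(length(runs) <= 3 && (length(runs) == 0 || runs[1] > 0) &&
                      sum(runs < 0) <= 1)
  first_max_hour <- min_hour <- NA_integer_
  if (!intermittent && shrink_hours > 0) {
    first_max_hour <- curve$hour[which.max(m)]
    after <- curve$hour >= first_max_hour
    min_hour <- curve$hour[after][which.min(m[after])]
  }
  list(curve = curve, shrink_hours = shrink_hours,
       first_max_hour = first_max_hour, min_hour = min_hour,
       intermittent = intermittent,
       n_days = length(unique(dd[ok])))
}

#' Hourly growth surfaces over (hour, VPD), (hour, REW) and (VPD, REW)
#'
#' Normalizes hourly growth to the tree-specific 99th percentile of positive
#' hourly growth (zero-growth hours included as zeros, so the surface
#' reflects both probability and rate), joins the hourly climate drivers,
#' and fits a [loess_surface()] for each requested predictor pair. Hour is
#' treated as a linear coordinate 0--23.
#'
#' @param part Partitioned series (one tree or several stacked trees with a
#'   `tree_id` column; normalization is per tree).
#' @param climate Hourly climate data.frame with `timestamp`, `vpd`, `rew`.
#' @param pairs Character vector among `"hour_vpd"`, `"hour_rew"`,
#'   `"vpd_rew"`.
#' @param span,degree,grid_res Passed to [loess_surface()].
#' @param max_points Upper bound on observations used per surface; larger
#'   inputs are subsampled reproducibly (local regression cost grows with
#'   n). `Inf` disables subsampling.
#' @param seed Seed for the subsample.
#' @return Named list of `hms_surface` objects.
#' @export
hourly_gro_surfaces <- function(part, climate,
                                pairs = c("hour_vpd", "hour_rew", "vpd_rew"),
                                span = 0.75, degree = 2, grid_res = 25,
                                max_points = 20000, seed = 1L) {
  pairs <- match.arg(pairs, several.ok = TRUE)
  tree <- part$tree_id %||% rep("tree", nrow(part))
  gnorm <- rep(NA_real_, nrow(part))
  for (tr in unique(tree)) {
    i <- tree == tr
    pos <- part$gro[i][part$gro[i] > 0]
    # a tree that never grew contributes zeros (no positive maximum to scale by)
    gnorm[i] <- if (length(pos) == 0) 0 else part$gro[i] / dp_quantile(pos, 0.99)
  }
  df <- data.frame(
    hour = dp_hour(part$timestamp),
    g = gnorm,
    vpd = climate$vpd[match(as.numeric(part$timestamp), as.numeric(climate$timestamp))],
    rew = climate$rew[match(as.numeric(part$timestamp), as.numeric(climate$timestamp))]
  )
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (is.finite(max_points) && nrow(df) > max_points) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    df <- df[sample.int(nrow(df), max_points), , drop = FALSE]
  }
  preds <- list(hour_vpd = c("hour", "vpd"), hour_rew = c("hour", "rew"),
                vpd_rew = c("vpd", "rew"))
  out <- lapply(pairs, function(p) {
    loess_surface(df[, preds[[p]]], df$g, span = span, degree = degree,
                  grid_res = grid_res)
  })
  stats::setNames(out, pairs)
}
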