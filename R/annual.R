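#' Cumulative annual growth
#'
#' Sum of hourly zero-growth increments over one calendar year (micrometres).
#'
#' @param part Partitioned series from [partition_zero_growth()].
#' @param year Calendar year.
#' @return Annual GRO in micrometres.
#' @export
annual_growth <- function(part, year) {
  sum(part$gro[dp_year(part$timestamp) == year])
}

#' Growing-season phenology from cumulative growth
#'
#' `gro_start` / `gro_end` are the first days of year whose end-of-day
#' cumulative growth reaches 5% / 95% of the annual total (ties to the
#' earliest DOY); `gro_length = gro_end - gro_start`.
#'
#' @inheritParams annual_growth
#' @return List with `gro_start`, `gro_end`, `gro_length` (all `NA` with a
#'   warning when annual growth is zero, for which phenology is undefined).
#' @export
growth_phenology <- function(part, year) {
  in_year <- dp_year(part$timestamp) == year
  total <- sum(part$gro[in_year])
  if (total <= 0) {
    warning("annual growth is zero in ", year, ": phenology undefined")
    return(list(gro_start = NA_integer_, gro_end = NA_integer_,
                gro_length = NA_integer_))
  }
  daily <- daily_growth_sums(part, year)
  cum <- cumsum(daily$gro_sum)
  gro_start <- daily$doy[which(cum >= 0.05 * total)[1]]
  gro_end <- daily$doy[which(cum >= 0.95 * total)[1]]
  list(gro_start = gro_start, gro_end = gro_end,
       gro_length = gro_end - gro_start)
}

# Daily summed growth for one year over the observed DOY range (absent days
# contribute 0 so the cumulative curve is defined on every DOY).
#' @noRd
daily_growth_sums <- function(part, year) {
  in_year <- dp_year(part$timestamp) == year
  doy <- dp_doy(part$timestamp[in_year])
  gro <- part$gro[in_year]
  all_doy <- seq(min(doy), max(doy))
  sums <- vapply(split(gro, factor(doy, levels = all_doy)),
                 function(x) sum(x), numeric(1))
  data.frame(doy = all_doy, gro_sum = unname(sums))
}

#' Growing-day and growing-hour counts
#'
#' `gro_hours` counts the hourly observations with positive growth over the
#' whole calendar year; `gro_days` counts the days containing at least one
#' such hour.
#'
#' @inheritParams annual_growth
#' @return List with `gro_days` and `gro_hours` (integer counts).
#' @export
growth_duration_counts <- function(part, year) {
  in_year <- dp_year(part$timestamp) == year
  growing <- part$gro[in_year] > 0
  list(
    gro_days = length(unique(dp_doy(part$timestamp[in_year])[growing])),
    gro_hours = sum(growing)
  )
}

#' Tree-water-deficit summaries for one year
#'
#' `twd_max` is the maximum hourly TWD, `twd_cum` the sum of hourly TWD
#' (micrometre-hours, TWD integrated at the native hourly step), and
#' `twd_gro_length_pct` the percentage of days within the growing season
#' (`gro_start`..`gro_end`, inclusive) with no growing hour -- the
#' complement of effective growth days.
#'
#' @inheritParams annual_growth
#' @param phenology Result of [growth_phenology()] for the same year.
#' @param shrink_day Definition of a non-effective day: `"no_growth"`
#'   (default; daily GRO = 0) or `"twd_positive"` (any hour with TWD > 0).
#' @return List with `twd_max`, `twd_cum`, `twd_gro_length_pct` (the latter
#'   `NA` when the season has zero length or phenology is undefined).
#' @export
twd_summaries <- function(part, year, phenology,
                          shrink_day = c("no_growth", "twd_positive")) {
  shrink_day <- match.arg(shrink_day)
  in_year <- dp_year(part$timestamp) == year
  twd <- part$twd[in_year]
  out <- list(twd_max = if (any(in_year)) max(twd) else NA_real_,
              twd_cum = sum(twd), twd_gro_length_pct = NA_real_)
  if (is.na(phenology$gro_start) || phenology$gro_length == 0) {
    if (!is.na(phenology$gro_start)) {
      warning("zero-length growing season in ", year,
              ": twd_gro_length_pct undefined")
    }
    return(out)
  }
  doy <- dp_doy(part$timestamp[in_year])
  season <- doy >= phenology$gro_start & doy <= phenology$gro_end
  season_days <- phenology$gro_end - phenology$gro_start + 1L
  flag <- if (shrink_day == "no_growth") part$gro[in_year] > 0 else part$twd[in_year] == 0
  effective <- length(unique(doy[season & flag]))
  out$twd_gro_length_pct <- dp_clamp(100 * (1 - effective / season_days), 0, 100)
  out
}

#' Cumulative climate drivers over the year and the growing season
#'
#' Sums of the daily median REW and VPD over the full calendar year and over
#' a season window (typically the measurement-set median `gro_start` to
#' `gro_end`).
#'
#' @param daily Daily climate from [daily_climate_summary()].
#' @param year Calendar year.
#' @param season_window Integer length-2 DOY interval (inclusive).
#' @return List with `rew_cum_year`, `vpd_cum_year`, `rew_cum_season`,
#'   `vpd_cum_season`.
#' @export
climate_cumulatives <- function(daily, year, season_window) {
  yr <- as.integer(format(daily$date, "%Y")) == year
  if (!any(yr)) stop("configuration error: daily climate does not cover ", year,
                     call. = FALSE)
  doy <- as.integer(format(daily$date, "%j"))
  if (length(season_window) != 2 || season_window[1] > season_window[2] ||
      season_window[1] < 1 || season_window[2] > 366) {
    stop("configuration error: season_window must be an increasing DOY pair within the year",
         call. = FALSE)
  }
  inwin <- yr & doy >= season_window[1] & doy <= season_window[2]
  s <- function(x, m) sum(x[m], na.rm = TRUE)
  list(
    rew_cum_year = s(daily$rew_daily, yr),
    vpd_cum_year = s(daily$vpd_daily, yr),
    rew_cum_season = s(daily$rew_daily, inwin),
    vpd_cum_season = s(daily$vpd_daily, inwin)
  )
}

#' Annual metric ledger for one tree-by-year series
#'
#' Assembles the full yearly record: annual GRO, growing-season phenology,
#' growth duration counts, TWD summaries, and (when daily climate is given)
#' cumulative REW/VPD over the year and season window.
#'
#' @inheritParams annual_growth
#' @param daily Optional daily climate from [daily_climate_summary()].
#' @param season_window Optional DOY interval for the climate season sums;
#'   defaults to this tree-year's own `gro_start`..`gro_end`.
#' @param tree_id Tree label carried into the output row.
#' @return One-row data.frame of annual metrics.
#' @export
annual_metrics <- function(part, year, daily = NULL, season_window = NULL,
                           tree_id = part$tree_id[1] %||% NA_character_) {
  gro <- annual_growth(part, year)
  phen <- suppressWarnings(growth_phenology(part, year))
  cnt <- growth_duration_counts(part, year)
  twd <- suppressWarnings(twd_summaries(part, year, phen))
  row <- data.frame(
    tree_id = tree_id, year = year, annual_gro = gro,
    gro_start = phen$gro_start, gro_end = phen$gro_end,
    gro_length = phen$gro_length,
    gro_days = cnt$gro_days, gro_hours = cnt$gro_hours,
    twd_max = twd$twd_max, twd_cum = twd$twd_cum,
    twd_gro_length_pct = twd$twd_gro_length_pct,
    stringsAsFactors = FALSE
  )
  if (!is.null(daily)) {
    if (is.null(season_window)) {
      season_window <- c(phen$gro_start, phen$gro_end)
    }
    cc <- if (anyNA(season_window)) {
      list(rew_cum_year = NA_real_, vpd_cum_year = NA_real_,
           rew_cum_season = NA_real_, vpd_cum_season = NA_real_)
    } else {
      climate_cumulatives(daily, year, season_window)
    }
    row <- cbind(row, as.data.frame(cc))
  }
  row
}

#' Measurement-set phenology medians
#'
#' A measurement set is a species-by-site combination of monitored trees.
#' Medians of `gro_start` and `gro_end` are taken over kept tree-by-year
#' records only and define the set's season window for climate cumulatives.
#'
#' @param metrics Data.frame of [annual_metrics()] rows with `species` and
#'   `site_id` columns attached.
#' @return One row per measurement set with median phenology and the member
#'   count.
#' @export
measurement_set_summary <- function(metrics) {
  key <- interaction(metrics$species, metrics$site_id, drop = TRUE)
  do.call(rbind, lapply(split(metrics, key), function(g) {
    data.frame(
      species = g$species[1], site_id = g$site_id[1],
      n_tree_years = nrow(g),
      n_trees = length(unique(g$tree_id)),
      median_gro_start = stats::median(g$gro_start, na.rm = TRUE),
      median_gro_end = stats::median(g$gro_end, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  }))
}
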