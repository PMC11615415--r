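#' Site calibration for relative extractable water
#'
#' Bundles the site-specific soil-moisture extremes used to rescale
#' volumetric soil water content (SWC, %) to relative extractable water
#' (REW): the lowest soil moisture recorded over the monitored period
#' (`swc_min`) and the field capacity (`swc_max`).
#'
#' @param site_id Character site label.
#' @param swc_min,swc_max Volumetric soil water content extremes (%).
#'   Both must be finite, non-negative, with `swc_max > swc_min`.
#' @return An object of class `site_calibration`.
#' @examples
#' site_calibration("mesic", swc_min = 12, swc_max = 61)
#' @export
site_calibration <- function(site_id, swc_min, swc_max) {
  stopifnot(is.character(site_id), length(site_id) == 1L)
  if (!is.finite(swc_min) || !is.finite(swc_max) || swc_min < 0 || swc_max < 0) {
    stop("swc_min and swc_max must be finite and >= 0", call. = FALSE)
  }
  if (swc_max <= swc_min) stop("swc_max must exceed swc_min", call. = FALSE)
  structure(list(site_id = site_id, swc_min = swc_min, swc_max = swc_max),
            class = "site_calibration")
}

#' Read a delimited climate table
#'
#' Reads a CSV or TSV climate file (delimiter chosen by extension), renames
#' columns via `column_map`, parses the timestamp column and returns records
#' sorted by time. Duplicate timestamps are an error; missing values are
#' preserved as `NA`.
#'
#' @param path File path; `.tsv`/`.txt` are read tab-delimited, anything
#'   else comma-delimited.
#' @param column_map Named character vector mapping standard names
#'   (`timestamp`, `t_air`, `rh_air`, `swc`, `rain`) to the file's column
#'   names, e.g. `c(timestamp = "TIMESTAMP", t_air = "TA")`. Unmapped
#'   standard names default to themselves.
#' @return A data.frame with a POSIXct `timestamp` column and whatever
#'   mapped driver columns the file provides, sorted by timestamp.
#' @export
read_climate_table <- function(path, column_map = NULL) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  std <- c("timestamp", "t_air", "rh_air", "swc", "rain")
  map <- stats::setNames(std, std)
  if (!is.null(column_map)) map[names(column_map)] <- unname(column_map)
  if (!map[["timestamp"]] %in% names(raw)) {
    stop("configuration error: timestamp column '", map[["timestamp"]],
         "' not found in ", path, call. = FALSE)
  }
  for (nm in names(column_map %||% character())) {
    if (!map[[nm]] %in% names(raw)) {
      stop("configuration error: mapped column '", map[[nm]],
           "' (for ", nm, ") not found in ", path, call. = FALSE)
    }
  }
  out <- data.frame(row.names = NULL)
  ts_chr <- as.character(raw[[map[["timestamp"]]]])
  ts <- as.POSIXct(rep(NA_real_, length(ts_chr)), origin = "1970-01-01", tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    todo <- is.na(ts)
    if (!any(todo)) break
    ts[todo] <- as.POSIXct(strptime(ts_chr[todo], fmt, tz = "UTC"))
  }
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1]
    stop("format error: unparseable timestamp '", ts_chr[bad],
         "' at data line ", bad, " of ", path, call. = FALSE)
  }
  out <- data.frame(timestamp = ts)
  for (nm in setdiff(std, "timestamp")) {
    if (map[[nm]] %in% names(raw)) out[[nm]] <- as.numeric(raw[[map[[nm]]]])
  }
  if (anyDuplicated(out$timestamp)) {
    dup <- out$timestamp[duplicated(out$timestamp)][1]
    stop("duplicate timestamp: ", format(dup, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
         call. = FALSE)
  }
  out[order(out$timestamp), , drop = FALSE]
}

#' Aggregate sub-hourly climate records to hourly values
#'
#' Per clock hour: mean of `t_air`, `rh_air` and `swc`; sum of `rain`.
#' Hours in which every reading of a variable is missing are `NA` for that
#' variable. The sub-hourly step must be constant within each hour.
#'
#' @param records Data.frame with `timestamp` and any of `t_air`, `rh_air`,
#'   `swc`, `rain` at a fixed sub-hourly step.
#' @return Hourly data.frame (timestamp at the hour start).
#' @export
aggregate_to_hourly <- function(records) {
  dp_stopifnot_sorted(records$timestamp, "climate records")
  hour_start <- as.POSIXct(trunc(records$timestamp, units = "hours"), tz = "UTC")
  key <- as.numeric(hour_start)
  steps <- tapply(as.numeric(records$timestamp), key, function(x) {
    if (length(x) > 1) unique(diff(x)) else numeric(0)
  })
  if (any(vapply(steps, function(s) length(s) > 1, logical(1)))) {
    stop("resolution error: mixed time steps within an hour", call. = FALSE)
  }
  grp <- factor(key, levels = unique(key))
  agg_mean <- function(v) as.numeric(tapply(v, grp, function(x) {
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  }))
  agg_sum <- function(v) as.numeric(tapply(v, grp, function(x) {
    if (all(is.na(x))) NA_real_ else sum(x, na.rm = TRUE)
  }))
  out <- data.frame(timestamp = as.POSIXct(as.numeric(levels(grp)),
                                           origin = "1970-01-01", tz = "UTC"))
  for (nm in c("t_air", "rh_air", "swc")) {
    if (nm %in% names(records)) out[[nm]] <- agg_mean(records[[nm]])
  }
  if ("rain" %in% names(records)) out$rain <- agg_sum(records$rain)
  out
}

#' Vapour pressure deficit from air temperature and relative humidity
#'
#' FAO-56 Tetens saturation vapour pressure:
#' \deqn{e_s(T) = 0.6108 \exp(17.27 T / (T + 237.3))}
#' and `vpd = e_s(t_air) * (1 - rh_air/100)` (kPa). Relative humidity
#' overshoots up to 100.5% (common sensor drift) are clamped to 100.
#'
#' @param t_air Air temperature (degrees C).
#' @param rh_air Relative humidity (%), in [0, 100.5].
#' @return VPD in kPa, always >= 0. `NA` inputs propagate.
#' @examples
#' compute_vpd(25, 100) # 0 at saturation
#' compute_vpd(20, 50)
#' @export
compute_vpd <- function(t_air, rh_air) {
  bad <- !is.na(rh_air) & (rh_air < 0 | rh_air > 100.5)
  if (any(bad)) {
    stop("validation error: rh_air outside [0, 100.5] (first offending value ",
         rh_air[bad][1], ")", call. = FALSE)
  }
  rh <- pmin(rh_air, 100)
  es <- 0.6108 * exp(17.27 * t_air / (t_air + 237.3))
  pmax(es * (1 - rh / 100), 0)
}

#' Relative extractable water from volumetric soil water content
#'
#' Linear rescaling `rew = (swc - swc_min) / (swc_max - swc_min)` between
#' the site-specific extremes. Values falling outside [0, 1] (readings
#' beyond the calibration extremes) are clamped; the number of clamped
#' values is attached as attribute `"n_clamped"` for QC logging.
#'
#' @param swc Volumetric soil water content (%); `NA` propagates.
#' @param cal A [site_calibration()].
#' @return REW in [0, 1] with attribute `n_clamped`.
#' @export
compute_rew <- function(swc, cal) {
  stopifnot(inherits(cal, "site_calibration"))
  rew <- (swc - cal$swc_min) / (cal$swc_max - cal$swc_min)
  n_clamped <- sum(rew < 0 | rew > 1, na.rm = TRUE)
  rew <- dp_clamp(rew, 0, 1)
  attr(rew, "n_clamped") <- n_clamped
  rew
}

#' Attach VPD and REW to an hourly climate table
#'
#' Convenience wrapper: computes `vpd` from `t_air`/`rh_air` and `rew`
#' from `swc`. If `cal` is `NULL`, the calibration defaults to the observed
#' min/max of the supplied `swc` series (the extremes of the monitored
#' record).
#'
#' @param hourly Hourly climate data.frame.
#' @param cal Optional [site_calibration()].
#' @return The input with `vpd` and `rew` columns added.
#' @export
derive_climate <- function(hourly, cal = NULL) {
  if (is.null(cal)) {
    rng <- range(hourly$swc, na.rm = TRUE)
    cal <- site_calibration("observed", rng[1], rng[2])
  }
  hourly$vpd <- compute_vpd(hourly$t_air, hourly$rh_air)
  hourly$rew <- as.numeric(compute_rew(hourly$swc, cal))
  hourly
}

#' Daily climate summary (median VPD and REW per day)
#'
#' The daily hydrometeorological drivers are the medians (50th percentile)
#' of the sub-daily VPD and REW values per day. Days without a single
#' non-missing hourly value for a variable are `NA`.
#'
#' @param hourly Hourly climate data.frame with `timestamp`, `vpd`, `rew`.
#' @return Data.frame with `date`, `vpd_daily`, `rew_daily`.
#' @export
daily_climate_summary <- function(hourly) {
  d <- dp_date(hourly$timestamp)
  med <- function(x) if (all(is.na(x))) NA_real_ else stats::median(x, na.rm = TRUE)
  grp <- factor(d, levels = unique(d))
  data.frame(
    date = as.Date(levels(grp)),
    vpd_daily = as.numeric(tapply(hourly$vpd, grp, med)),
    rew_daily = as.numeric(tapply(hourly$rew, grp, med))
  )
}
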