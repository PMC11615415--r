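# Internal helpers shared across modules. All timestamps in the package are
# POSIXct in a fixed-offset zone ("UTC" by convention): local standard time
# with no daylight-saving shifts, so clock hours are solar-anchored.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
dp_doy <- function(timestamp) as.POSIXlt(timestamp, tz = "UTC")$yday + 1L

#' @noRd
dp_year <- function(timestamp) as.POSIXlt(timestamp, tz = "UTC")$year + 1900L

#' @noRd
dp_hour <- function(timestamp) as.POSIXlt(timestamp, tz = "UTC")$hour

#' @noRd
dp_date <- function(timestamp) as.Date(timestamp, tz = "UTC")

#' @noRd
dp_clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Full hourly grid for one calendar year
#' @noRd
dp_year_hours <- function(year) {
  seq(
    from = as.POSIXct(sprintf("%d-01-01 00:00:00", year), tz = "UTC"),
    to   = as.POSIXct(sprintf("%d-12-31 23:00:00", year), tz = "UTC"),
    by   = "hour"
  )
}

#' @noRd
dp_stopifnot_sorted <- function(timestamp, what = "series") {
  if (anyNA(timestamp)) stop(what, ": timestamps contain missing values", call. = FALSE)
  d <- diff(as.numeric(timestamp))
  if (any(d <= 0)) {
    stop(what, ": timestamps must be strictly increasing (first violation at position ",
         which(d <= 0)[1] + 1L, ")", call. = FALSE)
  }
  invisible(TRUE)
}

# Quantile convention used everywhere: linear interpolation between order
# statistics (R type 7). Stated once so tests can pin it.
#' @noRd
dp_quantile <- function(x, p) {
  stats::quantile(x, probs = p, type = 7, names = FALSE, na.rm = TRUE)
}
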