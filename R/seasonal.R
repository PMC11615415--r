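#' Daily aggregation of hourly growth and water deficit
#'
#' Daily GRO and TWD are by default the within-day 99th percentile of the
#' hourly values (a robust sub-daily maximum excluding outliers; linear
#' interpolation between order statistics). A `sum` option gives the
#' physically additive daily growth total and is what the bimodal split
#' uses; `max` is the plain maximum.
#'
#' @param part Partitioned series from [partition_zero_growth()].
#' @param method One of `"p99"` (default), `"sum"`, `"max"`.
#' @return Data.frame with `date`, `doy`, `gro_daily`, `twd_daily`.
#' @export
daily_aggregate <- function(part, method = c("p99", "sum", "max")) {
  method <- match.arg(method)
  f <- switch(method,
              p99 = function(x) dp_quantile(x, 0.99),
              sum = function(x) sum(x, na.rm = TRUE),
              max = function(x) max(x, na.rm = TRUE))
  d <- dp_date(part$timestamp)
  grp <- factor(d, levels = unique(d))
  out <- data.frame(
    date = as.Date(levels(grp)),
    gro_daily = as.numeric(tapply(part$gro, grp, f)),
    twd_daily = as.numeric(tapply(part$twd, grp, f))
  )
  out$doy <- as.integer(format(out$date, "%j"))
  out[, c("date", "doy", "gro_daily", "twd_daily")]
}

#' Centred running mean
#'
#' 14-day (default) centred moving average; at the edges the mean is taken
#' over the available points (partial windows), so the output has the same
#' length as the input.
#'
#' @param x Numeric daily series.
#' @param window Window width in days (>= 1).
#' @return Smoothed numeric vector, same length as `x`.
#' @export
running_mean <- function(x, window = 14) {
  stopifnot(window >= 1)
  as.numeric(zoo::rollapply(zoo::zoo(x), width = window,
                            FUN = function(v) mean(v, na.rm = TRUE),
                            align = "center", partial = TRUE))
}

#' Spring/autumn split of annual growth at the day of maximum water deficit
#'
#' Bimodal Mediterranean growth shows a spring peak and a secondary autumn
#' peak separated by summer drought. The spring-to-autumn transition is set
#' at the DOY where the smoothed TWD reaches its maximum (earliest day on
#' ties); the spring percentage is the share of annual growth accumulated up
#' to and including that day, computed on summed daily growth so the two
#' percentages partition the annual total.
#'
#' @param daily Data.frame from [daily_aggregate()] with `doy` and
#'   `gro_daily` as daily growth sums (`method = "sum"`).
#' @param twd_smooth Smoothed daily TWD (from [running_mean()]), aligned
#'   with `daily`.
#' @param year Calendar year label carried into the output.
#' @param tree_id Tree label.
#' @return One-row data.frame with `transition_doy`, `spring_pct`,
#'   `autumn_pct` (all `NA` with a warning when annual growth is zero).
#' @export
bimodal_split <- function(daily, twd_smooth, year, tree_id = NA_character_) {
  stopifnot(length(twd_smooth) == nrow(daily))
  total <- sum(daily$gro_daily, na.rm = TRUE)
  if (total <= 0) {
    warning("annual growth is zero: bimodal split undefined")
    return(data.frame(tree_id = tree_id, year = year,
                      transition_doy = NA_integer_,
                      spring_pct = NA_real_, autumn_pct = NA_real_))
  }
  transition <- daily$doy[which.max(twd_smooth)]   # which.max: earliest tie
  spring <- 100 * sum(daily$gro_daily[daily$doy <= transition], na.rm = TRUE) / total
  data.frame(tree_id = tree_id, year = year, transition_doy = transition,
             spring_pct = spring, autumn_pct = 100 - spring)
}

#' Normalize a daily series to the tree-specific maximum
#'
#' Divides every daily value by the tree's 99th-percentile value taken
#' across the whole multi-year record, making trees of different size and
#' vigour comparable on the response surfaces. Values may exceed 1 (not
#' capped).
#'
#' @param x Daily values for one tree, all years pooled (>= 30 values).
#' @param q Quantile defining the tree-specific maximum (default 0.99).
#' @return Normalized vector with attribute `"scale"` (the divisor).
#' @export
normalize_to_tree_max <- function(x, q = 0.99) {
  if (sum(!is.na(x)) < 30) {
    stop("need at least 30 daily values per tree to define a stable maximum",
         call. = FALSE)
  }
  s <- dp_quantile(x, q)
  if (!is.finite(s) || s <= 0) {
    stop("tree-specific ", q, " quantile is zero: normalization undefined; ",
         "exclude this tree from surfaces", call. = FALSE)
  }
  structure(x / s, scale = s)
}
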