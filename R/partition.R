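#' Convert stem circumference to diameter
#'
#' Band dendrometers record circumference; all downstream quantities are on
#' the diameter scale assuming a circular stem: `diameter = circumference / pi`.
#'
#' @param circumference Circumference in micrometres, >= 0.
#' @return Diameter in micrometres.
#' @export
circumference_to_diameter <- function(circumference) {
  if (any(circumference < 0, na.rm = TRUE)) {
    stop("validation error: circumference must be >= 0", call. = FALSE)
  }
  circumference / pi
}

#' Annual quality-control gate for a dendrometer series
#'
#' A tree-by-year series is excluded whenever a temporal gap or a run of
#' exactly constant (artefactual) readings longer than `max_run_days`
#' overlaps the growing-season gate window. Runs are measured in hours on
#' the year's full hourly grid, so leading/trailing missing stretches count
#' as gaps; "exceeding" is strict (a run of exactly `max_run_days` is kept).
#'
#' @param series Data.frame with `timestamp` (hourly POSIXct) and `diameter`
#'   (micrometres) covering `year` at least partially.
#' @param year Calendar year to assess.
#' @param gate_window Integer length-2 DOY interval (inclusive) standing in
#'   for the growing season; default 60--330.
#' @param max_run_days Threshold run length in days (default 7).
#' @param flat_tol Absolute tolerance for "constant" readings (default 0:
#'   exact equality, appropriate at 1 micrometre sensor resolution).
#' @return A one-row data.frame (`tree_id` if present, `year`, `status`
#'   "kept"/"dropped", `reason`, `longest_gap_days`, `longest_flat_days`).
#' @export
qc_annual_gate <- function(series, year, gate_window = c(60L, 330L),
                           max_run_days = 7, flat_tol = 0) {
  tree_id <- if (!is.null(series$tree_id)) series$tree_id[1] else NA_character_
  report <- function(status, reason, gap, flat) {
    data.frame(tree_id = tree_id, year = year, status = status, reason = reason,
               longest_gap_days = gap, longest_flat_days = flat,
               stringsAsFactors = FALSE)
  }
  in_year <- dp_year(series$timestamp) == year
  s <- series[in_year, , drop = FALSE]
  if (nrow(s) == 0 || all(is.na(s$diameter))) {
    return(report("dropped", "no data", NA_real_, NA_real_))
  }
  dp_stopifnot_sorted(s$timestamp, "dendrometer series")
  grid <- dp_year_hours(year)
  doy <- dp_doy(grid)
  idx <- match(as.numeric(grid), as.numeric(s$timestamp))
  val <- s$diameter[idx]                       # NA where hour unobserved
  max_run_h <- max_run_days * 24

  run_table <- function(flag) {                # runs of TRUE: start index, length
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & !is.na(r$values)
    data.frame(start = starts[keep], len = r$lengths[keep])
  }
  overlaps_gate <- function(runs) {
    if (nrow(runs) == 0) return(logical(0))
    vapply(seq_len(nrow(runs)), function(i) {
      d <- doy[runs$start[i]:(runs$start[i] + runs$len[i] - 1L)]
      any(d >= gate_window[1] & d <= gate_window[2])
    }, logical(1))
  }

  gaps <- run_table(is.na(val))
  # flat runs: consecutive equal readings among observed hours; a run of n
  # equal values spans n hours on the hourly grid
  flat_flag <- c(FALSE, abs(diff(val)) <= flat_tol) & !is.na(val) &
    c(FALSE, !is.na(val[-length(val)]))
  flat_flag[is.na(flat_flag)] <- FALSE
  fr <- run_table(flat_flag)
  if (nrow(fr) > 0) {                          # include the run's first reading
    fr$start <- fr$start - 1L
    fr$len <- fr$len + 1L
  }

  longest_gap <- if (nrow(gaps)) max(gaps$len) / 24 else 0
  longest_flat <- if (nrow(fr)) max(fr$len) / 24 else 0
  bad_gap <- gaps$len > max_run_h & overlaps_gate(gaps)
  bad_flat <- fr$len > max_run_h & overlaps_gate(fr)

  if (any(bad_gap) || any(bad_flat)) {
    reason <- paste(c(
      if (any(bad_gap)) sprintf("gap of %.1f days in gate window",
                                max(gaps$len[bad_gap]) / 24),
      if (any(bad_flat)) sprintf("flat run of %.1f days in gate window",
                                 max(fr$len[bad_flat]) / 24)
    ), collapse = "; ")
    return(report("dropped", reason, longest_gap, longest_flat))
  }
  report("kept", "", longest_gap, longest_flat)
}

#' Partition a stem-diameter series under the zero-growth concept
#'
#' Assumes no irreversible growth occurs while the stem is shrunken below
#' its previous maximum diameter. With `M(t) = max_{s<=t} D(s)` the running
#' maximum:
#' \itemize{
#'   \item growth `gro(t) = max(0, D(t) - M(t-1))` (new wood beyond the
#'     historical maximum),
#'   \item tree water deficit `twd(t) = M(t) - D(t)` (reversible stem-water
#'     depletion).
#' }
#' The first observation initialises `M = D`, `gro = 0`, `twd = 0`. Missing
#' hours are simply absent rows: the running maximum carries over and growth
#' across a gap is attributed to the first observation after it.
#'
#' @param series Data.frame with strictly increasing `timestamp` and
#'   `diameter` (micrometres); rows with `NA` diameter are dropped.
#' @return The input rows plus `running_max`, `gro`, `twd` columns.
#' @examples
#' s <- data.frame(
#'   timestamp = as.POSIXct("2020-01-01", tz = "UTC") + 3600 * (0:3),
#'   diameter = c(10, 12, 11, 13)
#' )
#' partition_zero_growth(s)[, c("gro", "twd")]
#' @export
partition_zero_growth <- function(series) {
  s <- series[!is.na(series$diameter), , drop = FALSE]
  if (nrow(s) == 0) stop("empty series after removing missing diameters", call. = FALSE)
  dp_stopifnot_sorted(s$timestamp, "dendrometer series")
  m <- cummax(s$diameter)
  prev_max <- c(s$diameter[1], m[-length(m)])
  s$running_max <- m
  s$gro <- pmax(0, s$diameter - prev_max)
  s$twd <- m - s$diameter
  s
}
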