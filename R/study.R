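#' Configuration for an end-to-end study run
#'
#' Assembles and validates the options of [run_study()]. The default study
#' is fully synthetic: `trees` describes the monitored population (one row
#' per tree: `tree_id`, `species`, `site_id`) and each site gets its own
#' simulated climate; species are distinguished by an `autumn_fraction`
#' override per species if given.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Master seed; all stage seeds derive from it.
#' @param trees Data.frame with `tree_id`, `species`, `site_id`.
#' @param scenario Named list of [synthetic_config()] overrides (applied to
#'   every tree) or a list of such lists keyed by species.
#' @param artifacts Optional artefact specs per tree: data.frame with
#'   `tree_id`, `year`, `start_doy`, `length_days`, `type`.
#' @param gate_window,daily_method,span,degree,grid_res,max_surface_points
#'   Analysis options (defaults: DOY 60--330, `"p99"`, 0.75, 2, 25, 20000).
#' @param hourly_surfaces Logical: also fit the hour-resolved growth
#'   surfaces (slower; default TRUE).
#' @return List of class `study_config`.
#' @export
study_config <- function(out_dir, seed = 1L,
                         trees = data.frame(
                           tree_id = c("T1", "T2"),
                           species = c("sp1", "sp1"),
                           site_id = c("site1", "site1"),
                           stringsAsFactors = FALSE),
                         scenario = list(), artifacts = NULL,
                         gate_window = c(60L, 330L),
                         daily_method = "p99",
                         span = 0.75, degree = 2, grid_res = 25,
                         max_surface_points = 20000,
                         hourly_surfaces = TRUE) {
  known <- names(formals(study_config))
  stopifnot(all(c("tree_id", "species", "site_id") %in% names(trees)))
  if (length(scenario) && is.null(names(scenario))) {
    stop("configuration error: scenario must be a named list", call. = FALSE)
  }
  structure(as.list(environment())[known], class = "study_config")
}

#' Run the full dendrometer study pipeline
#'
#' Simulate (or accept) per-tree stem series and site climates, apply the
#' annual QC gate, partition each kept tree-year under the zero-growth
#' concept, and derive every downstream product: the annual metric ledger
#' (with measurement-set season windows for the climate cumulatives), daily
#' seasonal series and bimodal splits, normalized response surfaces over the
#' VPD-by-REW space, diel profiles with night/day summaries, midnight-zeroed
#' diel curves, and (optionally) hour-resolved growth surfaces. All tables
#' are written as tidy CSVs under `config$out_dir` together with a JSON run
#' manifest; re-running with an identical config reproduces identical files.
#'
#' @param config A [study_config()].
#' @return The manifest (invisibly a list): seed, parameter echo, per-stage
#'   record counts, file inventory.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  trees <- config$trees
  counts <- list(trees = nrow(trees))

  scenario_for <- function(species) {
    sc <- config$scenario
    if (length(sc) && all(vapply(sc, is.list, logical(1))) &&
        species %in% names(sc)) sc <- sc[[species]]
    do.call(synthetic_config, sc)
  }

  # --- climate per site -----------------------------------------------------
  sites <- unique(trees$site_id)
  climates <- list()
  for (i in seq_along(sites)) {
    cfg <- scenario_for(trees$species[trees$site_id == sites[i]][1])
    climates[[sites[i]]] <- simulate_climate(cfg, seed = config$seed + 1000L * i)
  }

  # --- stems, artefacts, QC, partition --------------------------------------
  parts <- list(); truth_rows <- list(); qc_rows <- list()
  for (k in seq_len(nrow(trees))) {
    tr <- trees[k, ]
    cfg <- scenario_for(tr$species)
    sim <- simulate_stem(climates[[tr$site_id]], cfg,
                         seed = config$seed + k, tree_id = tr$tree_id)
    series <- sim$series
    if (!is.null(config$artifacts)) {
      sp <- config$artifacts[config$artifacts$tree_id == tr$tree_id, , drop = FALSE]
      if (nrow(sp)) series <- inject_artifacts(series, sp)$series
    }
    truth_rows[[k]] <- sim$truth_annual
    yrs <- sort(unique(dp_year(series$timestamp)))
    kept <- list()
    for (y in yrs) {
      rep_y <- qc_annual_gate(series, y, gate_window = config$gate_window)
      qc_rows[[length(qc_rows) + 1L]] <- rep_y
      if (rep_y$status == "kept") {
        s_y <- series[dp_year(series$timestamp) == y, , drop = FALSE]
        kept[[as.character(y)]] <- s_y
      }
    }
    if (length(kept)) {
      p <- partition_zero_growth(do.call(rbind, kept))
      p$species <- tr$species; p$site_id <- tr$site_id
      parts[[tr$tree_id]] <- p
    }
  }
  qc <- do.call(rbind, qc_rows)
  truth <- do.call(rbind, truth_rows)
  counts$tree_years_seen <- nrow(qc)
  counts$tree_years_kept <- sum(qc$status == "kept")

  # --- daily climate --------------------------------------------------------
  daily_by_site <- lapply(climates, daily_climate_summary)

  # --- annual metrics (two passes: phenology, then set-median windows) ------
  ann <- list()
  for (id in names(parts)) {
    p <- parts[[id]]
    for (y in unique(dp_year(p$timestamp))) {
      m <- annual_metrics(p, y, tree_id = id)
      m$species <- p$species[1]; m$site_id <- p$site_id[1]
      ann[[length(ann) + 1L]] <- m
    }
  }
  annual <- do.call(rbind, ann)
  sets <- measurement_set_summary(annual)
  cc <- lapply(seq_len(nrow(annual)), function(i) {
    s <- sets[sets$species == annual$species[i] & sets$site_id == annual$site_id[i], ]
    win <- c(s$median_gro_start, s$median_gro_end)
    if (anyNA(win)) {
      list(rew_cum_year = NA_real_, vpd_cum_year = NA_real_,
           rew_cum_season = NA_real_, vpd_cum_season = NA_real_)
    } else {
      climate_cumulatives(daily_by_site[[annual$site_id[i]]], annual$year[i],
                          round(win))
    }
  })
  annual <- cbind(annual, do.call(rbind, lapply(cc, as.data.frame)))
  counts$annual_records <- nrow(annual)

  # --- seasonal: daily series, smoothing, bimodal split ---------------------
  seasonal <- list(); bimodal <- list()
  for (id in names(parts)) {
    p <- parts[[id]]
    day_disp <- daily_aggregate(p, method = config$daily_method)
    day_sum <- daily_aggregate(p, method = "sum")
    day_disp$gro_smooth <- running_mean(day_disp$gro_daily)
    day_disp$twd_smooth <- running_mean(day_disp$twd_daily)
    day_disp$tree_id <- id
    seasonal[[id]] <- day_disp
    for (y in unique(as.integer(format(day_disp$date, "%Y")))) {
      iy <- as.integer(format(day_disp$date, "%Y")) == y
      bimodal[[paste(id, y)]] <- suppressWarnings(
        bimodal_split(day_sum[iy, ], day_disp$twd_smooth[iy], y, tree_id = id))
    }
  }
  seasonal <- do.call(rbind, seasonal)
  bimodal <- do.call(rbind, bimodal)

  # --- HMS surfaces per measurement set -------------------------------------
  hms_grids <- list()
  for (si in seq_len(nrow(sets))) {
    sel <- trees$tree_id[trees$species == sets$species[si] &
                           trees$site_id == sets$site_id[si]]
    sel <- intersect(sel, names(parts))
    if (!length(sel)) next
    site <- sets$site_id[si]
    dclim <- daily_by_site[[site]]
    pool <- list()
    for (id in sel) {
      sd_tree <- seasonal[seasonal$tree_id == id, ]
      gnorm <- try(normalize_to_tree_max(sd_tree$gro_daily), silent = TRUE)
      tnorm <- try(normalize_to_tree_max(sd_tree$twd_daily), silent = TRUE)
      if (inherits(gnorm, "try-error") || inherits(tnorm, "try-error")) next
      j <- match(sd_tree$date, dclim$date)
      pool[[id]] <- data.frame(vpd = dclim$vpd_daily[j], rew = dclim$rew_daily[j],
                               gro_norm = as.numeric(gnorm), twd_norm = as.numeric(tnorm))
    }
    if (!length(pool)) next
    pool <- do.call(rbind, pool)
    pool <- pool[stats::complete.cases(pool), ]
    hull <- hms_hull(pool[, c("vpd", "rew")])
    for (resp in c("gro_norm", "twd_norm")) {
      surf <- loess_surface(pool[, c("vpd", "rew")], pool[[resp]],
                            span = config$span, degree = config$degree,
                            grid_res = config$grid_res, hull = hull)
      g <- surf$grid
      g$response <- resp
      g$species <- sets$species[si]; g$site_id <- site
      hms_grids[[paste(si, resp)]] <- g
    }
  }
  hms_grids <- if (length(hms_grids)) do.call(rbind, hms_grids) else NULL

  # --- diel profiles, night/day summaries, diel delta-D ---------------------
  profiles <- list(); nd <- list(); deltad <- list()
  for (id in names(parts)) {
    p <- parts[[id]]
    for (y in unique(dp_year(p$timestamp))) {
      profiles[[paste(id, y)]] <- diel_profile(p, y, tree_id = id)
    }
    for (df in c("all", "growing")) {
      dd <- diel_delta_d(p, day_filter = df)
      deltad[[paste(id, df)]] <- data.frame(
        tree_id = id, day_filter = df, dd$curve,
        shrink_hours = dd$shrink_hours, intermittent = dd$intermittent)
    }
  }
  profiles <- do.call(rbind, profiles)
  for (si in seq_len(nrow(sets))) {
    sel <- trees$tree_id[trees$species == sets$species[si] &
                           trees$site_id == sets$site_id[si]]
    pr <- profiles[profiles$tree_id %in% sel, , drop = FALSE]
    if (!nrow(pr)) next
    trend <- median_trend(pr)
    s <- night_day_summary(trend)
    s$species <- sets$species[si]; s$site_id <- sets$site_id[si]
    nd[[si]] <- s
  }
  nd <- do.call(rbind, nd)
  deltad <- do.call(rbind, deltad)

  # --- hourly growth surfaces (pooled per set) ------------------------------
  hourly_grids <- NULL
  if (isTRUE(config$hourly_surfaces) && length(parts)) {
    hg <- list()
    for (si in seq_len(nrow(sets))) {
      sel <- intersect(trees$tree_id[trees$species == sets$species[si] &
                                       trees$site_id == sets$site_id[si]],
                       names(parts))
      if (!length(sel)) next
      pp <- do.call(rbind, parts[sel])
      surfs <- hourly_gro_surfaces(pp, climates[[sets$site_id[si]]],
                                   span = config$span, degree = config$degree,
                                   grid_res = config$grid_res,
                                   max_points = config$max_surface_points,
                                   seed = config$seed)
      for (nm in names(surfs)) {
        g <- surfs[[nm]]$grid
        g$pair <- nm; g$species <- sets$species[si]; g$site_id <- sets$site_id[si]
        names(g)[1:2] <- c("x1", "x2")
        hg[[paste(si, nm)]] <- g
      }
    }
    hourly_grids <- if (length(hg)) do.call(rbind, hg) else NULL
  }

  # --- write ----------------------------------------------------------------
  wr <- function(x, name) {
    if (is.null(x)) return(NULL)
    path <- file.path(config$out_dir, name)
    utils::write.csv(x, path, row.names = FALSE)
    name
  }
  part_out <- do.call(rbind, lapply(names(parts), function(id) {
    p <- parts[[id]]
    data.frame(tree_id = id, timestamp = format(p$timestamp, "%Y-%m-%dT%H:%M:%S"),
               diameter_um = p$diameter, running_max_um = p$running_max,
               gro_um = p$gro, twd_um = p$twd)
  }))
  files <- c(
    wr(qc, "qc_report.csv"),
    wr(part_out, "partitioned.csv"),
    wr(annual, "annual_metrics.csv"),
    wr(sets, "measurement_sets.csv"),
    wr(seasonal, "seasonal_daily.csv"),
    wr(bimodal, "bimodal_summary.csv"),
    wr(hms_grids, "hms_surfaces.csv"),
    wr(profiles, "diel_profiles.csv"),
    wr(nd, "night_day_summary.csv"),
    wr(deltad, "diel_delta_d.csv"),
    wr(hourly_grids, "hourly_gro_surfaces.csv"),
    wr(truth, "synthetic_truth_annual.csv")
  )
  manifest <- list(
    package_version = as.character(utils::packageVersion("dendropart")),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("trees", "artifacts"))],
    counts = counts,
    files = files
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}

#' Validate the cross-module invariants of a completed run directory
#'
#' Re-reads the emitted files and asserts the pipeline's structural
#' invariants: the zero-growth conservation identity and exclusion rule on
#' the partitioned series, diel contribution sums of 100 per tree-year with
#' growth, bimodal percentages partitioning 100, and percentage bounds in
#' the annual ledger.
#'
#' @param run_dir Directory produced by [run_study()].
#' @param tol Numeric tolerance for the sum checks (default 1e-9).
#' @return Data.frame with one row per check (`check`, `ok`, `detail`).
#' @export
validate_outputs <- function(run_dir, tol = 1e-9) {
  checks <- list()
  add <- function(check, ok, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, ok = ok, detail = detail, stringsAsFactors = FALSE)
  }
  rd <- function(name) utils::read.csv(file.path(run_dir, name))

  p <- rd("partitioned.csv")
  cons_dev <- vapply(split(p, p$tree_id), function(g) {
    resid <- g$diameter_um + g$twd_um - cumsum(g$gro_um)
    max(abs(resid - resid[1]))
  }, numeric(1))
  add("conservation identity", all(cons_dev <= 1e-6 * max(p$diameter_um)),
      sprintf("max deviation %.3g um", max(cons_dev)))
  add("exclusion rule (GRO>0 => TWD=0)", !any(p$gro_um > 0 & p$twd_um > 0),
      sprintf("%d violations", sum(p$gro_um > 0 & p$twd_um > 0)))
  add("non-negativity", all(p$gro_um >= 0) && all(p$twd_um >= 0), "")

  pr <- rd("diel_profiles.csv")
  sums <- tapply(pr$contribution, interaction(pr$tree_id, pr$year),
                 function(x) if (all(is.na(x))) NA_real_ else sum(x))
  sums <- sums[!is.na(sums)]
  add("contribution sum", all(abs(sums - 100) <= 1e-6),
      sprintf("max |sum-100| = %.3g", if (length(sums)) max(abs(sums - 100)) else 0))

  b <- rd("bimodal_summary.csv")
  bs <- b$spring_pct + b$autumn_pct
  add("bimodal percentages partition 100",
      all(abs(bs[!is.na(bs)] - 100) <= tol * 100), "")

  a <- rd("annual_metrics.csv")
  pct_ok <- all(a$twd_gro_length_pct >= 0 & a$twd_gro_length_pct <= 100, na.rm = TRUE)
  add("percentage bounds", pct_ok, "")
  add("phenology ordering",
      all(a$gro_start <= a$gro_end, na.rm = TRUE) &&
        all(a$gro_length == a$gro_end - a$gro_start, na.rm = TRUE), "")
  add("growing hours >= growing days", all(a$gro_hours >= a$gro_days), "")

  do.call(rbind, checks)
}
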