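# Hydrometeorological-space (HMS) geometry and local polynomial surfaces.
# The HMS is the bivariate plane of atmospheric drought (VPD, kPa) and soil
# drought (REW, unitless) over which normalized growth/dehydration responses
# are mapped.

#' Trimmed convex hull of the hydrometeorological space
#'
#' Defines the admissible region of drought conditions: the convex hull of
#' the daily (VPD, REW) cloud after discarding the fraction of points
#' farthest from the cloud centre -- extreme conditions such as heavy-rain
#' saturation. Distances are Euclidean after standardizing each axis to unit
#' variance; the number excluded is `ceiling(exclude_frac * n)`.
#'
#' @param points Data.frame or matrix with two columns (vpd, rew); >= 10
#'   distinct points.
#' @param exclude_frac Fraction of farthest points to discard (default 0.01).
#' @return List with `hull` (polygon vertex data.frame, original units, in
#'   hull order), `kept` and `excluded` (row indices into `points`),
#'   `centre` (axis means).
#' @export
hms_hull <- function(points, exclude_frac = 0.01) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  ok <- stats::complete.cases(pts)
  if (nrow(unique(pts[ok, , drop = FALSE])) < 10) {
    stop("need at least 10 distinct points to define a hull", call. = FALSE)
  }
  idx_ok <- which(ok)
  p <- pts[idx_ok, , drop = FALSE]
  sds <- apply(p, 2, stats::sd)
  if (any(sds == 0)) stop("degenerate-hull error: a coordinate is constant", call. = FALSE)
  z <- sweep(p, 2, colMeans(p), `-`)
  z <- sweep(z, 2, sds, `/`)
  d <- sqrt(rowSums(z^2))
  n_drop <- ceiling(exclude_frac * nrow(p))
  excluded <- if (n_drop > 0) idx_ok[order(d, decreasing = TRUE)[seq_len(n_drop)]] else integer(0)
  kept <- setdiff(idx_ok, excluded)
  kp <- pts[kept, , drop = FALSE]
  h <- grDevices::chull(kp[, 1], kp[, 2])
  if (length(h) < 3) stop("degenerate-hull error: points are collinear", call. = FALSE)
  hull <- as.data.frame(kp[h, , drop = FALSE])
  names(hull) <- colnames(points)[1:2] %||% c("x1", "x2")
  list(hull = hull, kept = kept, excluded = excluded, centre = colMeans(p))
}

#' Local polynomial (loess-type) regression surface over two predictors
#'
#' Fits the classic local regression estimator from first principles: at
#' each query point the `ceiling(span * n)` nearest observations (Euclidean
#' distance after standardizing each predictor to unit variance) are given
#' tricube weights `(1 - (d/d_max)^3)^3` and a bivariate polynomial of the
#' requested degree is fitted by weighted least squares; the prediction is
#' the fitted value at the query point. A rank-deficient local quadratic
#' falls back to degree 1 at that node (recorded in the output).
#'
#' Predictions are evaluated on a regular grid over the bounding box of the
#' trimmed hull and flagged by hull membership; values outside the hull are
#' `NA`.
#'
#' @param x Two-column matrix/data.frame of predictors (e.g. vpd, rew).
#' @param y Numeric response (normalized GRO or TWD), same length.
#' @param span Fraction of points in each local neighbourhood (default 0.75).
#' @param degree Local polynomial degree, 1 or 2 (default 2).
#' @param grid_res Grid cells per axis (default 25).
#' @param hull Optional result of [hms_hull()] on (a superset of) `x`; if
#'   `NULL` it is computed from `x` with `exclude_frac = 0.01`.
#' @return Object of class `hms_surface`: list with `grid` (long data.frame:
#'   both predictors, `prediction`, `inside_hull`, `degree_used`), `hull`,
#'   `span`, `degree`, and `predict_fun(newx)` for arbitrary query points.
#' @export
loess_surface <- function(x, y, span = 0.75, degree = 2, grid_res = 25,
                          hull = NULL) {
  X <- as.matrix(x)[, 1:2, drop = FALSE]
  keep <- stats::complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]
  yy <- as.numeric(y)[keep]
  n <- nrow(X)
  if (n < 30) stop("need at least 30 points for a local regression surface", call. = FALSE)
  stopifnot(degree %in% 1:2, span > 0, span <= 1)
  if (is.null(hull)) hull <- hms_hull(X, exclude_frac = 0.01)

  ctr <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0] <- 1
  Z <- sweep(sweep(X, 2, ctr, `-`), 2, sds, `/`)
  k <- ceiling(span * n)

  fit_at <- function(q) {                       # q: length-2 raw coords
    zq <- (q - ctr) / sds
    d2 <- (Z[, 1] - zq[1])^2 + (Z[, 2] - zq[2])^2
    dk2 <- sort(d2, partial = k)[k]
    idx <- which(d2 <= dk2)
    if (length(idx) > k) idx <- idx[order(d2[idx])][seq_len(k)]
    d <- sqrt(d2[idx])
    dmax <- max(d)
    w <- if (dmax == 0) rep(1, length(idx)) else (1 - pmin(d / dmax, 1)^3)^3
    # guard: if the far points carry zero weight, keep a floor so the normal
    # equations stay well posed for near-duplicate designs
    if (all(w == 0)) w <- rep(1, length(idx))
    u1 <- X[idx, 1] - q[1]; u2 <- X[idx, 2] - q[2]
    B <- if (degree == 2) cbind(1, u1, u2, u1^2, u2^2, u1 * u2) else cbind(1, u1, u2)
    sw <- sqrt(w)
    fit <- stats::lm.fit(B * sw, yy[idx] * sw)
    deg_used <- degree
    if (degree == 2 && fit$rank < ncol(B)) {    # rank-deficient: degree-1 fallback
      B <- cbind(1, u1, u2)
      fit <- stats::lm.fit(B * sw, yy[idx] * sw)
      deg_used <- 1
    }
    c(prediction = unname(fit$coefficients[1]), degree_used = deg_used)
  }

  hx <- hull$hull[[1]]; hy <- hull$hull[[2]]
  gx <- seq(min(hx), max(hx), length.out = grid_res)
  gy <- seq(min(hy), max(hy), length.out = grid_res)
  grid <- expand.grid(gx, gy, KEEP.OUT.ATTRS = FALSE)
  names(grid) <- names(hull$hull)
  inside <- mgcv::in.out(cbind(hx, hy), as.matrix(grid))
  grid$prediction <- NA_real_
  grid$degree_used <- NA_integer_
  if (any(inside)) {
    res <- t(vapply(which(inside), function(i) fit_at(as.numeric(grid[i, 1:2])),
                    numeric(2)))
    grid$prediction[inside] <- res[, 1]
    grid$degree_used[inside] <- as.integer(res[, 2])
  }
  grid$inside_hull <- inside

  structure(list(
    grid = grid, hull = hull, span = span, degree = degree,
    predict_fun = function(newx) {
      nx <- as.matrix(newx)
      apply(nx, 1, function(q) fit_at(as.numeric(q))[1])
    }
  ), class = "hms_surface")
}

#' @export
print.hms_surface <- function(x, ...) {
  cat("Local polynomial surface (span", x$span, ", degree", x$degree, ")\n")
  cat(sum(x$grid$inside_hull), "of", nrow(x$grid), "grid nodes inside hull\n")
  invisible(x)
}
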