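# Independent oracles and small fixture builders. Each oracle is a direct,
# unoptimised restatement of the definition, kept independent of the package
# internals it checks.

hourly_series <- function(diameters, start = "2020-01-01 00:00:00",
                          tree_id = NULL) {
  out <- data.frame(
    timestamp = as.POSIXct(start, tz = "UTC") + 3600 * (seq_along(diameters) - 1),
    diameter = diameters
  )
  if (!is.null(tree_id)) out <- cbind(tree_id = tree_id, out)
  out
}

# O(n^2) prefix-maximum brute force for the zero-growth partition
oracle_partition <- function(d) {
  n <- length(d)
  gro <- twd <- rmax <- numeric(n)
  for (t in seq_len(n)) {
    rmax[t] <- max(d[1:t])
    prev <- if (t == 1) d[1] else max(d[1:(t - 1)])
    gro[t] <- max(0, d[t] - prev)
    twd[t] <- rmax[t] - d[t]
  }
  list(running_max = rmax, gro = gro, twd = twd)
}

# sort-and-middle median
oracle_median <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0) return(NA_real_)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

# linear interpolation between order statistics (hand-rolled, matches the
# stated percentile convention)
oracle_quantile <- function(x, p) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

oracle_running_mean <- function(x, window) {
  n <- length(x)
  before <- floor((window - 1) / 2)
  after <- window - 1 - before
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - before):min(n, i + after)], na.rm = TRUE)
  }, numeric(1))
}

# direct weighted-least-squares local fit at a single query point: explicit
# normal equations, no shared code with the package implementation
oracle_local_fit <- function(X, y, q, span, degree = 2) {
  n <- nrow(X)
  mu <- colMeans(X); sdv <- apply(X, 2, sd)
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  zq <- (q - mu) / sdv
  d <- sqrt((Z[, 1] - zq[1])^2 + (Z[, 2] - zq[2])^2)
  k <- ceiling(span * n)
  idx <- order(d)[1:k]
  dmax <- max(d[idx])
  w <- (1 - pmin(d[idx] / dmax, 1)^3)^3
  u1 <- X[idx, 1] - q[1]; u2 <- X[idx, 2] - q[2]
  B <- if (degree == 2) cbind(1, u1, u2, u1^2, u2^2, u1 * u2) else cbind(1, u1, u2)
  beta <- solve(t(B) %*% (B * w), t(B) %*% (y[idx] * w))
  beta[1]
}

polygon_area <- function(px, py) {
  n <- length(px)
  j <- c(n, seq_len(n - 1))
  abs(sum(px * py[j] - px[j] * py)) / 2
}

write_temp_csv <- function(df, ext = ".csv") {
  path <- tempfile(fileext = ext)
  utils::write.csv(df, path, row.names = FALSE)
  path
}
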