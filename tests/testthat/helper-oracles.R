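# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Fourier amplitude at frequency f by dense trapezoidal quadrature over an
# integer number of periods.
quadrature_f1 <- function(x, f, rate) {
  t <- (seq_along(x) - 1) / rate
  n_per <- floor(t[length(t)] * f)
  keep <- t < n_per / f + 1e-12
  t <- t[keep]; x <- x[keep]
  ftrap <- function(y) {
    (sum(y) - (y[1] + y[length(y)]) / 2) / (length(y) - 1)
  }
  span <- t[length(t)] - t[1]
  re <- ftrap(x * cos(2 * pi * f * t))
  im <- ftrap(x * sin(2 * pi * f * t))
  2 * sqrt(re^2 + im^2)
}

# OLS slope from the closed-form normal equations.
ols_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * y) / sum(xc^2)
}

# 1-D Wasserstein-1 by numerical integration of |F1 - F2| on a fine grid.
grid_wasserstein <- function(x, y, n_grid = 200000) {
  lo <- min(x, y) - 1e-9
  hi <- max(x, y) + 1e-9
  g <- seq(lo, hi, length.out = n_grid)
  Fx <- stats::ecdf(x)(g)
  Fy <- stats::ecdf(y)(g)
  sum(abs(Fx - Fy)) * (hi - lo) / n_grid
}

# Convex hull area by gift wrapping (Jarvis march) + the triangle-fan shoelace
# formula; independent of grDevices::chull.
giftwrap_hull_area <- function(p) {
  n <- nrow(p)
  start <- which.min(p[, 1])
  hull <- start
  repeat {
    cur <- hull[length(hull)]
    cand <- setdiff(seq_len(n), cur)
    nxt <- cand[1]
    for (k in cand[-1]) {
      cross <- (p[nxt, 1] - p[cur, 1]) * (p[k, 2] - p[cur, 2]) -
        (p[nxt, 2] - p[cur, 2]) * (p[k, 1] - p[cur, 1])
      if (cross < 0 ||
          (cross == 0 && sum((p[k, ] - p[cur, ])^2) > sum((p[nxt, ] - p[cur, ])^2))) {
        nxt <- k
      }
    }
    if (nxt == start) break
    hull <- c(hull, nxt)
  }
  v <- p[hull, , drop = FALSE]
  m <- nrow(v)
  abs(sum(v[, 1] * v[c(2:m, 1), 2] - v[c(2:m, 1), 1] * v[, 2])) / 2
}

# Build trial rows with an exact target pairwise correlation matrix from an
# orthonormal basis (Cholesky construction).
trials_with_correlations <- function(R, n_time = 64) {
  stopifnot(isSymmetric(R))
  L <- chol(R)  # R = t(L) %*% L
  M <- scale(matrix(stats::rnorm(n_time * (nrow(R) + 1)), n_time),
             center = TRUE, scale = FALSE)
  basis <- qr.Q(qr(M))[, seq_len(nrow(R))]  # zero-mean orthonormal columns
  t(basis %*% L)  # rows are trials with exact pairwise correlations R
}

# A hand-built STRF object for filter-extraction tests.
synthetic_strf <- function(kernel, dt = 0.05, dx = 5) {
  n_lag <- nrow(kernel); n_x <- ncol(kernel)
  xs <- (seq_len(n_x) - (n_x + 1) / 2) * dx
  structure(list(kernel = kernel, lags_s = (seq_len(n_lag) - 1) * dt,
                 space_deg = xs, space_x = xs, space_y = 0,
                 space_dim = c(1L, n_x), update_rate = 1 / dt,
                 window = n_lag * dt, amplitude = max(abs(kernel)),
                 snr = max(abs(kernel)) / mean(abs(kernel)), accepted = TRUE),
            class = "strf")
}
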