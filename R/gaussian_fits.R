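# Gaussian receptive-field fits (1-D spatial filters and 2-D RF centers).
# Nonlinear least squares by bounded quasi-Newton with moment-based
# initialization; non-convergence is flagged on the result, never raised.

FWHM_FACTOR <- 2 * sqrt(2 * log(2))  # 2.3548...

#' Fit a 1-D Gaussian to a spatial profile
#'
#' Model `f(x) = a exp(-(x - mu)^2 / (2 sigma^2))`, fitted by least squares.
#' Initialization: `a` at the profile maximum, `mu` at its location, `sigma`
#' from the second moment. The FWHM is `2 sqrt(2 ln 2) sigma`.
#'
#' @param x Positions (degrees).
#' @param y Profile values (use the absolute profile for OFF filters).
#' @return An object of class `gaussian1d_fit`: `a`, `mu`, `sigma`, `fwhm`,
#'   `residual` (RSS), `fitted`, `converged`.
#' @examples
#' x <- seq(-20, 20, 0.5)
#' fit_gaussian_1d(x, 2 * exp(-(x - 3)^2 / (2 * 4.25^2)))$fwhm  # ~10
#' @export
fit_gaussian_1d <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  span <- diff(range(x))
  i0 <- which.max(y)
  w <- pmax(y - min(y), 0)
  sigma0 <- if (sum(w) > 0) {
    sqrt(sum(w * (x - x[i0])^2) / sum(w))
  } else span / 4
  sigma0 <- min(max(sigma0, span / 100), span)
  obj <- function(p) sum((p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2)) - y)^2)
  opt <- try(stats::optim(c(y[i0], x[i0], sigma0), obj, method = "L-BFGS-B",
                          lower = c(-Inf, min(x) - span, span * 1e-4),
                          upper = c(Inf, max(x) + span, span * 2)),
             silent = TRUE)
  if (inherits(opt, "try-error") || !is.finite(opt$value)) {
    return(structure(list(a = NA_real_, mu = NA_real_, sigma = NA_real_,
                          fwhm = NA_real_, residual = NA_real_,
                          fitted = rep(NA_real_, length(x)),
                          converged = FALSE),
                     class = "gaussian1d_fit"))
  }
  p <- opt$par
  structure(list(a = p[1], mu = p[2], sigma = p[3],
                 fwhm = FWHM_FACTOR * p[3], residual = opt$value,
                 fitted = p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2)),
                 converged = opt$convergence == 0),
            class = "gaussian1d_fit")
}

#' @export
print.gaussian1d_fit <- function(x, ...) {
  cat(sprintf("1-D Gaussian fit: a = %.4g, mu = %.4g deg, sigma = %.4g deg, FWHM = %.4g deg%s\n",
              x$a, x$mu, x$sigma, x$fwhm,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Fit a 2-D Gaussian to a spatial receptive field
#'
#' Model `f(x, y) = h exp(-(((cx - x)/wx)^2 + ((cy - y)/wy)^2) / 2)` (the
#' widths are the Gaussian standard deviations along each axis), fitted by
#' least squares on the full grid. The amplitude may be negative (OFF
#' receptive fields); initialization uses the extremum of largest magnitude.
#'
#' @param z Response matrix `[y, x]`.
#' @param x_deg,y_deg Coordinates of the columns / rows, degrees.
#' @return An object of class `gaussian2d_fit`: `h`, `center_x`, `center_y`,
#'   `width_x`, `width_y`, `residual`, `converged`.
#' @export
fit_gaussian_2d <- function(z, x_deg, y_deg) {
  stopifnot(is.matrix(z), length(x_deg) == ncol(z), length(y_deg) == nrow(z))
  xg <- matrix(x_deg, nrow(z), ncol(z), byrow = TRUE)
  yg <- matrix(y_deg, nrow(z), ncol(z))
  i0 <- which.max(abs(z))
  h0 <- z[i0]
  spanx <- max(diff(range(x_deg)), 1e-6)
  spany <- max(diff(range(y_deg)), 1e-6)
  w <- pmax(sign(h0) * z, 0)
  sw <- sum(w)
  cx0 <- if (sw > 0) sum(w * xg) / sw else xg[i0]
  cy0 <- if (sw > 0) sum(w * yg) / sw else yg[i0]
  wx0 <- if (sw > 0) max(sqrt(sum(w * (xg - cx0)^2) / sw), spanx / 50) else spanx / 4
  wy0 <- if (sw > 0) max(sqrt(sum(w * (yg - cy0)^2) / sw), spany / 50) else spany / 4
  model <- function(p) {
    p[1] * exp(-(((p[2] - xg) / p[4])^2 + ((p[3] - yg) / p[5])^2) / 2)
  }
  obj <- function(p) sum((model(p) - z)^2)
  opt <- try(stats::optim(c(h0, cx0, cy0, wx0, wy0), obj, method = "L-BFGS-B",
                          lower = c(-Inf, min(x_deg) - spanx, min(y_deg) - spany,
                                    spanx * 1e-3, spany * 1e-3),
                          upper = c(Inf, max(x_deg) + spanx, max(y_deg) + spany,
                                    spanx * 2, spany * 2)),
             silent = TRUE)
  if (inherits(opt, "try-error") || !is.finite(opt$value)) {
    return(structure(list(h = NA_real_, center_x = NA_real_,
                          center_y = NA_real_, width_x = NA_real_,
                          width_y = NA_real_, residual = NA_real_,
                          converged = FALSE),
                     class = "gaussian2d_fit"))
  }
  p <- opt$par
  structure(list(h = p[1], center_x = p[2], center_y = p[3],
                 width_x = p[4], width_y = p[5], residual = opt$value,
                 converged = opt$convergence == 0),
            class = "gaussian2d_fit")
}

#' @export
print.gaussian2d_fit <- function(x, ...) {
  cat(sprintf("2-D Gaussian fit: h = %.4g at (%.4g, %.4g) deg, widths (%.4g, %.4g) deg%s\n",
              x$h, x$center_x, x$center_y, x$width_x, x$width_y,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}
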