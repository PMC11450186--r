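# Recording-analysis pipeline: dF/F, trial reliability, F1 amplitudes,
# log-luminance slopes, OFF-edge responses, contrast-luminance heatmaps,
# reverse-correlation STRFs and their filters.

#' Relative fluorescence change (dF/F)
#'
#' `(F - F0) / F0` per ROI. The baseline F0 is either the mean of the whole
#' trace (default) or the mean of the first seconds of the recording (the
#' full-field prelude used with white-noise stimulation).
#'
#' @param traces Numeric vector (one ROI) or matrix `[roi, time]`.
#' @param baseline_mode `"trace_mean"` or `"prelude_mean"`.
#' @param frame_rate Sampling rate in Hz (required for `"prelude_mean"`).
#' @param prelude_s Prelude duration in seconds (default 4).
#' @return dF/F with the shape of `traces`.
#' @examples
#' dff(c(1, 3))  # baseline 2 -> c(-0.5, 0.5)
#' @export
dff <- function(traces, baseline_mode = c("trace_mean", "prelude_mean"),
                frame_rate = NULL, prelude_s = 4) {
  baseline_mode <- match.arg(baseline_mode)
  one <- function(v, id) {
    f0 <- if (baseline_mode == "trace_mean") {
      mean(v)
    } else {
      if (is.null(frame_rate)) stop_invalid("'frame_rate' required for prelude baseline")
      n0 <- max(1L, round(prelude_s * frame_rate))
      mean(v[seq_len(min(n0, length(v)))])
    }
    if (!is.finite(f0) || f0 <= 0) {
      stop_invalid("non-positive baseline for ROI %s", id)
    }
    (v - f0) / f0
  }
  if (is.matrix(traces)) {
    out <- t(vapply(seq_len(nrow(traces)),
                    function(i) one(traces[i, ], rownames(traces)[i] %||% i),
                    numeric(ncol(traces))))
    dimnames(out) <- dimnames(traces)
    out
  } else one(traces, "1")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trial-to-trial reliability of an ROI
#'
#' Mean of the pairwise Pearson correlations between trials; ROIs below the
#' threshold (default 0.6) are flagged for exclusion.
#'
#' @param trials Matrix `[trial, time]` with >= 2 trials.
#' @param threshold Keep threshold on the reliability value.
#' @return List with `reliability`, `keep`, and `defined` (`FALSE` when a
#'   zero-variance trial makes the correlation undefined).
#' @export
roi_reliability <- function(trials, threshold = 0.6) {
  if (!is.matrix(trials) || nrow(trials) < 2) {
    stop_invalid("need a [trial, time] matrix with >= 2 trials")
  }
  sds <- apply(trials, 1, stats::sd)
  if (any(sds == 0)) {
    return(list(reliability = NA_real_, keep = FALSE, defined = FALSE))
  }
  cors <- stats::cor(t(trials))
  rel <- mean(cors[upper.tri(cors)])
  # small tolerance so values at the threshold are kept despite round-off
  list(reliability = rel, keep = rel >= threshold - 1e-9, defined = TRUE)
}

#' Fourier amplitude at the stimulus frequency (F1)
#'
#' Single-sided Fourier amplitude of a response trace at the grating temporal
#' frequency, evaluated over a whole number of stimulus periods: a pure
#' sinusoid of amplitude A returns A. The frequency is matched to the nearest
#' DFT bin (within half a bin).
#'
#' @param trace Response time series.
#' @param stimulus_frequency Stimulus temporal frequency, Hz.
#' @param frame_rate Sampling rate, Hz (must exceed twice the frequency).
#' @return The F1 amplitude.
#' @examples
#' t <- seq(0, 4 - 0.1, by = 0.1)
#' f1_amplitude(2 * sin(2 * pi * t), 1, 10)  # 2
#' @export
f1_amplitude <- function(trace, stimulus_frequency, frame_rate) {
  check_number(stimulus_frequency, "stimulus_frequency", lower = 1e-12)
  if (stimulus_frequency > frame_rate / 2) {
    stop_invalid("stimulus frequency %g Hz above Nyquist (%g Hz)",
                 stimulus_frequency, frame_rate / 2)
  }
  n <- length(trace)
  n_periods <- floor(n * stimulus_frequency / frame_rate)
  if (n_periods < 2) {
    stop_invalid("trace must cover at least 2 stimulus periods (has %.3g)",
                 n * stimulus_frequency / frame_rate)
  }
  n_use <- round(n_periods * frame_rate / stimulus_frequency)
  n_use <- min(n_use, n)
  x <- trace[seq_len(n_use)]
  k_exact <- stimulus_frequency * n_use / frame_rate
  k <- round(k_exact)
  if (abs(k - k_exact) > 0.5 + 1e-9) {
    stop_invalid("stimulus frequency does not align with a DFT bin")
  }
  2 * Mod(sum(x * exp(-2i * pi * k * (seq_len(n_use) - 1) / n_use))) / n_use
}

#' Luminance dependence of contrast responses
#'
#' Ordinary least-squares slope of response versus log10 luminance; slope 0
#' means luminance-invariant responses, positive slopes a luminance-scaling
#' neuron, negative slopes low-luminance enhancement.
#'
#' @param luminance Mean luminance per condition (> 0), >= 2 distinct values.
#' @param response Contrast response per condition.
#' @return The slope (response units per decade of luminance).
#' @export
luminance_slope <- function(luminance, response) {
  if (length(unique(luminance)) < 2) {
    stop_invalid("need >= 2 distinct luminances for a slope")
  }
  if (any(luminance <= 0)) stop_invalid("luminances must be > 0")
  unname(stats::coef(stats::lm(response ~ log10(luminance)))[2])
}

#' OFF-edge response metric
#'
#' Difference between the peak response in the edge window and the mean
#' response during the preceding full-field second.
#'
#' @param trace Response time series (dF/F).
#' @param frame_rate Sampling rate, Hz.
#' @param edge_onset Time of edge onset, seconds from trace start.
#' @param edge_duration Duration of the edge window, seconds.
#' @param pre_duration Length of the preceding baseline window, seconds.
#' @return Peak-minus-baseline response value.
#' @export
edge_response <- function(trace, frame_rate, edge_onset, edge_duration,
                          pre_duration = 1) {
  i_on <- round(edge_onset * frame_rate) + 1L
  i_pre <- i_on - round(pre_duration * frame_rate)
  i_end <- i_on + round(edge_duration * frame_rate) - 1L
  if (i_pre < 1 || i_on <= i_pre || i_end > length(trace)) {
    stop_invalid("edge/pre windows fall outside the trace")
  }
  pre_idx <- seq(i_pre, i_on - 1L)
  edge_idx <- seq(i_on, i_end)
  max(trace[edge_idx]) - mean(trace[pre_idx])
}

## ---- contrast-luminance heatmap ---------------------------------------------

# Bilinear (order-1) zoom with endpoint alignment: output grids span the same
# corners as the input, so linear ramps are reproduced exactly.
bilinear_zoom <- function(mat, zoom) {
  nr <- nrow(mat); nc <- ncol(mat)
  nro <- nr * zoom; nco <- nc * zoom
  ri <- seq(1, nr, length.out = nro)
  ci <- seq(1, nc, length.out = nco)
  r0 <- pmin(floor(ri), nr - 1L); rf <- ri - r0
  c0 <- pmin(floor(ci), nc - 1L); cf <- ci - c0
  out <- matrix(0, nro, nco)
  for (j in seq_len(nco)) {
    a <- mat[cbind(r0, c0[j])] * (1 - rf) + mat[cbind(r0 + 1L, c0[j])] * rf
    b <- mat[cbind(r0, c0[j] + 1L)] * (1 - rf) + mat[cbind(r0 + 1L, c0[j] + 1L)] * rf
    out[, j] <- a * (1 - cf[j]) + b * cf[j]
  }
  out
}

#' Contrast-luminance response heatmap
#'
#' Interpolates a grid of mean contrast responses (contrasts x luminances)
#' with an order-1 (bilinear) spline zoom -- the default zoom of 5 turns a
#' 5 x 5 grid into 25 x 25 -- then smooths with a Gaussian filter (sigma in
#' zoomed-grid pixels) and computes evenly spaced iso-response contour levels.
#'
#' @param grid Complete numeric response matrix (no missing cells).
#' @param zoom Integer zoom factor.
#' @param smooth_sigma Gaussian sigma in zoomed-grid pixels.
#' @param n_contours Number of contour levels.
#' @return An object of class `contrast_luminance_map` with `base`,
#'   `interpolated`, `smoothed`, `levels`, and a `degenerate` flag for
#'   constant maps.
#' @export
contrast_luminance_map <- function(grid, zoom = 5, smooth_sigma = 10,
                                   n_contours = 8) {
  if (!is.matrix(grid) || any(!is.finite(grid))) {
    stop_invalid("'grid' must be a complete numeric matrix")
  }
  interp <- bilinear_zoom(grid, zoom)
  smoothed <- gaussian_smooth_2d(interp, smooth_sigma)
  rng <- range(smoothed)
  degenerate <- diff(rng) < .Machine$double.eps * max(1, abs(rng[2]))
  levels <- if (degenerate) rep(rng[1], n_contours) else {
    seq(rng[1], rng[2], length.out = n_contours + 2)[seq_len(n_contours) + 1]
  }
  structure(list(base = grid, interpolated = interp, smoothed = smoothed,
                 zoom = zoom, smooth_sigma = smooth_sigma, levels = levels,
                 degenerate = degenerate),
            class = "contrast_luminance_map")
}

#' @export
print.contrast_luminance_map <- function(x, ...) {
  cat(sprintf("Contrast-luminance map: %d x %d -> %d x %d (zoom %d, sigma %g)%s\n",
              nrow(x$base), ncol(x$base), nrow(x$interpolated),
              ncol(x$interpolated), x$zoom, x$smooth_sigma,
              if (x$degenerate) " [degenerate: constant map]" else ""))
  invisible(x)
}

#' @export
plot.contrast_luminance_map <- function(x, ...) {
  graphics::image(x$smoothed, ...)
  if (!x$degenerate) graphics::contour(x$smoothed, levels = x$levels, add = TRUE)
  invisible(x)
}

## ---- reverse correlation ----------------------------------------------------

#' Spatiotemporal receptive field by reverse correlation
#'
#' Estimates the STRF of an ROI from its response to ternary white noise:
#' the trace is linearly interpolated to the 20 Hz stimulus update rate,
#' converted to dF/F against the prelude baseline, mean-centered, and
#' correlated with the level-coded stimulus (levels 0/0.5/1 mapped to
#' -1/0/+1) over a backward window:
#' `STRF(tau, x) = 1/(T - tau) * sum_t r_t s_x(t - tau)`.
#'
#' @param trace Raw fluorescence trace, sampled at `trace_rate`, starting at
#'   the movie start (prelude included).
#' @param movie A ternary-noise [stimulus_movie()] (from
#'   [make_ternary_noise()]).
#' @param trace_rate Sampling rate of `trace`, Hz.
#' @param window Backward window length in seconds (default 2).
#' @param prelude_s Prelude length used as dF/F baseline, seconds.
#' @return An object of class `strf`: `kernel` (lag x space, space flattened
#'   y-major for 2-D noise), `lags_s`, `space_deg`, `space_dim`,
#'   `update_rate`, `amplitude`, `snr`.
#' @export
compute_strf <- function(trace, movie, trace_rate, window = 2,
                         prelude_s = 4) {
  stopifnot(inherits(movie, "stimulus_movie"))
  d <- dim(movie$frames)
  nT <- d[1]
  rate <- movie$frame_rate
  n_lag <- round(window * rate)
  if (length(trace) / trace_rate < window) {
    stop_invalid("trace (%.3g s) shorter than the STRF window (%g s)",
                 length(trace) / trace_rate, window)
  }
  # resample the trace onto the stimulus update grid
  t_trace <- (seq_along(trace) - 1) / trace_rate
  t_stim <- (seq_len(nT) - 1) / rate
  r <- stats::approx(t_trace, trace, xout = t_stim, rule = 2)$y
  r <- dff(r, "prelude_mean", frame_rate = rate, prelude_s = prelude_s)
  r <- r - mean(r)
  # stimulus centered around 0: levels {0, 0.5, 1} -> {-1, 0, +1}
  s <- matrix(2 * movie$frames - 1, nrow = nT)
  if (nT <= n_lag) stop_invalid("movie shorter than the STRF window")
  kernel <- matrix(0, n_lag, ncol(s))
  for (lag in seq_len(n_lag) - 1L) {
    idx <- (lag + 1L):nT
    kernel[lag + 1L, ] <- crossprod(r[idx], s[idx - lag, , drop = FALSE]) / (nT - lag)
  }
  space_dim <- d[2:3]
  xs <- (seq_len(d[3]) - (d[3] + 1) / 2) * movie$degrees_per_pixel
  ys <- (seq_len(d[2]) - (d[2] + 1) / 2) * movie$degrees_per_pixel
  amp <- max(abs(kernel))
  structure(list(kernel = kernel, lags_s = (seq_len(n_lag) - 1) / rate,
                 space_deg = if (d[2] == 1L) xs else NULL,
                 space_x = xs, space_y = ys, space_dim = space_dim,
                 update_rate = rate, window = window, amplitude = amp,
                 snr = amp / mean(abs(kernel)), accepted = NA),
            class = "strf")
}

#' @export
print.strf <- function(x, ...) {
  cat(sprintf("STRF: %d lags x %d spatial positions (%g s window at %g Hz)\n",
              nrow(x$kernel), ncol(x$kernel), x$window, x$update_rate))
  cat(sprintf("  amplitude %.4g, SNR %.3g%s\n", x$amplitude, x$snr,
              if (is.na(x$accepted)) "" else if (x$accepted) ", accepted" else ", rejected"))
  invisible(x)
}

#' Filter noisy STRFs
#'
#' Default mode keeps STRFs whose peak absolute amplitude reaches 0.005; the
#' low-SNR mode (for noisier indicators) lowers the amplitude threshold to
#' 0.003 but additionally requires SNR >= 10. SNR is the peak absolute kernel
#' value divided by the mean absolute kernel value; set `snr_literal = TRUE`
#' for the plain mean in the denominator (numerically unstable for
#' sign-balanced kernels).
#'
#' @param strfs A list of [compute_strf()] results (or a single one).
#' @param mode `"default"` or `"low_snr"`.
#' @param amplitude_threshold,snr_threshold Override the mode's thresholds.
#' @param snr_literal Use `mean(kernel)` instead of `mean(abs(kernel))`.
#' @return The accepted subset (a list), each with `accepted = TRUE`; the
#'   `"rejected"` attribute carries the rejected ones.
#' @export
filter_strfs <- function(strfs, mode = c("default", "low_snr"),
                         amplitude_threshold = NULL, snr_threshold = NULL,
                         snr_literal = FALSE) {
  mode <- match.arg(mode)
  if (inherits(strfs, "strf")) strfs <- list(strfs)
  amp_thr <- amplitude_threshold %||% if (mode == "default") 0.005 else 0.003
  snr_thr <- snr_threshold %||% if (mode == "default") NA_real_ else 10
  decide <- function(s) {
    ok <- s$amplitude >= amp_thr
    if (!is.na(snr_thr)) {
      snr <- if (snr_literal) s$amplitude / mean(s$kernel) else s$snr
      ok <- ok && is.finite(snr) && snr >= snr_thr
    }
    ok
  }
  keep <- vapply(strfs, decide, logical(1))
  acc <- lapply(strfs[keep], function(s) { s$accepted <- TRUE; s })
  rej <- lapply(strfs[!keep], function(s) { s$accepted <- FALSE; s })
  attr(acc, "rejected") <- rej
  acc
}

#' Extract spatial and temporal filters from an STRF
#'
#' The temporal filter is the time course at the spatial position of the
#' kernel's minimum, and the spatial filter the spatial profile at the lag of
#' the minimum (minima because OFF-cell STRF amplitudes are negative; ties
#' break to the first occurrence scanning space within each lag). A 1-D
#' Gaussian is fitted to the absolute spatial profile and the FWHM reported
#' as `2 sqrt(2 ln 2) sigma` (= 2.3548 sigma).
#'
#' @param strf A [compute_strf()] result (1-D spatial noise).
#' @return An object of class `strf_filters`: `temporal` and `spatial` data
#'   frames, the `fit` ([fit_gaussian_1d()]), and `fwhm` (degrees; `NA` when
#'   the fit did not converge, which is flagged, not an error).
#' @export
extract_filters <- function(strf) {
  stopifnot(inherits(strf, "strf"))
  k <- strf$kernel
  # row-major (space fastest) first-occurrence argmin
  m <- which(t(k) == min(k), arr.ind = TRUE)[1, ]
  x_star <- m[1]; tau_star <- m[2]
  temporal <- data.frame(lag_s = strf$lags_s, value = k[, x_star])
  xd <- strf$space_deg %||% strf$space_x
  spatial <- data.frame(x_deg = xd, value = k[tau_star, ])
  fit <- fit_gaussian_1d(spatial$x_deg, abs(spatial$value))
  structure(list(temporal = temporal, spatial = spatial, fit = fit,
                 fwhm = if (fit$converged) fit$fwhm else NA_real_,
                 argmin = c(lag = unname(tau_star), space = unname(x_star))),
            class = "strf_filters")
}

#' @export
print.strf_filters <- function(x, ...) {
  cat(sprintf("STRF filters: minimum at lag %.3g s, %.3g deg; FWHM %.4g deg%s\n",
              x$temporal$lag_s[x$argmin["lag"]],
              x$spatial$x_deg[x$argmin["space"]], x$fwhm,
              if (x$fit$converged) "" else " [fit did not converge]"))
  invisible(x)
}

#' Map a receptive-field center with a 2-D Gaussian
#'
#' Fits the two-dimensional Gaussian
#' `f(x, y) = h exp(-(((cx - x)/wx)^2 + ((cy - y)/wy)^2) / 2)` to the spatial
#' receptive field at the lag of the STRF minimum (OFF cells), returning the
#' fitted center for stimulus placement. Also accepts a plain spatial
#' response matrix.
#'
#' @param x A [compute_strf()] result from 2-D (checkerboard) noise, or a
#'   numeric matrix `[y, x]`.
#' @param x_deg,y_deg Pixel-center coordinates when `x` is a matrix.
#' @return A [fit_gaussian_2d()] object (fields `h`, `center_x`, `center_y`,
#'   `width_x`, `width_y`, `residual`, `converged`).
#' @export
map_rf_center <- function(x, x_deg = NULL, y_deg = NULL) {
  if (inherits(x, "strf")) {
    tau_star <- which(t(x$kernel) == min(x$kernel), arr.ind = TRUE)[1, 2]
    frame <- matrix(x$kernel[tau_star, ], x$space_dim[1], x$space_dim[2])
    fit_gaussian_2d(frame, x$space_x, x$space_y)
  } else {
    if (!is.matrix(x)) stop_invalid("need an strf or a spatial response matrix")
    if (is.null(x_deg)) x_deg <- seq_len(ncol(x))
    if (is.null(y_deg)) y_deg <- seq_len(nrow(x))
    fit_gaussian_2d(x, x_deg, y_deg)
  }
}
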