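# Shunting-inhibition divisive-normalization circuit model of the
# transmedullary neurons Tm1 and Tm9.
#
# The Tm response in the pseudo-stationary regime is
#   R(t) = I(t) / (g_l + J(t)^p),
# where I(t) is the main columnar lamina-neuron input (L2 for Tm1, L3 for
# Tm9), J(t) the summed lamina input pooled by a wide-field neuron over
# columns within the pooling diameter, g_l a leak conductance and p the
# normalization exponent (1 linear, Tm1; 2 quadratic, Tm9).

#' Normalization-circuit parameters
#'
#' @param g_l Leak conductance (> 0). The default was obtained with
#'   [calibrate_leak_conductance()]: the value that makes the linear (p = 1)
#'   model maximally luminance-invariant at 15 deg pooling under the standard
#'   grating protocol.
#' @param p Normalization exponent (integer; 1 for Tm1, 2 for Tm9).
#' @param pooling_diameter Pooling extent in degrees (15 deg spans three
#'   medulla columns at the 5 deg column pitch).
#' @param input_cell Label of the columnar input (`"L2"` for Tm1, `"L3"` for
#'   Tm9).
#' @param input_params [membrane_params()] of the columnar input model.
#' @param column_pitch Column spacing in degrees of visual space.
#' @return An object of class `normalization_params`.
#' @export
normalization_params <- function(g_l = 0.332, p = 1, pooling_diameter = 15,
                                 input_cell = c("L2", "L3"),
                                 input_params = membrane_params(),
                                 column_pitch = 5) {
  check_number(g_l, "g_l", lower = 1e-12)
  if (p != round(p) || p < 1) stop_invalid("'p' must be a positive integer")
  check_number(pooling_diameter, "pooling_diameter", lower = 1e-9)
  input_cell <- match.arg(input_cell)
  structure(list(g_l = g_l, p = as.integer(p),
                 pooling_diameter = pooling_diameter, input_cell = input_cell,
                 input_params = input_params, column_pitch = column_pitch),
            class = "normalization_params")
}

#' @export
print.normalization_params <- function(x, ...) {
  cat(sprintf("Normalization circuit (%s input): g_l = %.4g, p = %d, pooling %g deg (%d columns)\n",
              x$input_cell, x$g_l, x$p, x$pooling_diameter,
              length(column_offsets(x))))
  invisible(x)
}

# Column positions (degrees) of the pooled region: a 1-D row at the column
# pitch spanning the pooling diameter, centered on the main column.
column_offsets <- function(params) {
  n <- max(1L, floor(params$pooling_diameter / params$column_pitch))
  (seq_len(n) - (n + 1) / 2) * params$column_pitch
}

#' Pool columnar input responses
#'
#' The wide-field pooling signal `J(t)`: the sum of the input-cell responses
#' over all columns in the pooled region, as a plain sum (not a mean).
#'
#' @param input_responses Matrix `[time, columns]` (or a vector for a single
#'   column) of input-cell response series.
#' @return Numeric vector `J(t)`.
#' @export
pool_inputs <- function(input_responses) {
  if (is.null(input_responses) || length(input_responses) == 0) {
    stop_invalid("empty pooling region")
  }
  if (is.matrix(input_responses)) rowSums(input_responses)
  else as.numeric(input_responses)
}

#' Tm response under shunting-inhibition normalization
#'
#' Elementwise `I / (g_l + J^p)` in the pseudo-stationary regime.
#'
#' @param I Main columnar input series.
#' @param J Pooled input series (same length, >= 0). `J = 0` everywhere
#'   degenerates to pure leak scaling `I / g_l` (no gain control).
#' @param params A [normalization_params()].
#' @return Response series.
#' @export
tm_response <- function(I, J, params) {
  stopifnot(inherits(params, "normalization_params"))
  if (length(I) != length(J)) stop_invalid("'I' and 'J' must have equal length")
  if (any(J < 0)) stop_invalid("pooled input must be >= 0")
  den <- params$g_l + J^params$p
  if (any(den == 0)) stop_invalid("g_l + J^p vanishes: division degenerate")
  I / den
}

#' Simulate Tm contrast-response curves across luminance
#'
#' For every mean luminance, `n_traces` sinusoidal stimuli with random phases
#' (uniform on `[0, 2 pi)`, simulating different spatial locations) drive the
#' columnar input model in each pooled column, with per-column spatial phase
#' offsets set by the column positions and the grating wavelength. The Tm
#' response is the center column's input divided by `g_l + J^p`, and the
#' contrast response is the mean F1 amplitude across traces. The luminance
#' dependence is summarized as the OLS slope of F1 versus log10 luminance,
#' both for the normalized Tm response and for the un-normalized columnar
#' input.
#'
#' @param params A [normalization_params()].
#' @param mean_luminances Grating mean luminances in model units
#'   (1e4 photons s^-1 photoreceptor^-1); defaults to the standard five
#'   levels.
#' @param contrast Michelson contrast.
#' @param temporal_frequency Grating temporal frequency, Hz.
#' @param spatial_wavelength Grating wavelength, degrees.
#' @param n_traces Number of random-phase traces per luminance.
#' @param duration,sim_rate Simulated epoch length (s) and rate (Hz).
#' @param seed Integer seed for the phase draws (`phases` overrides).
#' @param phases Optional fixed phase vector (radians) replacing the draws.
#' @return An object of class `circuit_curves`: `curve` (data frame with
#'   `mean_luminance`, `F1_tm`, `F1_input`), `slope_tm`, `slope_input`, and
#'   the simulation metadata.
#' @examples
#' cc <- simulate_contrast_curves(normalization_params(p = 1), n_traces = 50)
#' cc$slope_tm / cc$slope_input
#' @export
simulate_contrast_curves <- function(params,
                                     mean_luminances = c(1.2, 2.6, 5.3, 7.9, 10.6),
                                     contrast = 1, temporal_frequency = 1,
                                     spatial_wavelength = 30, n_traces = 1000,
                                     duration = 4, sim_rate = 100, seed = 1L,
                                     phases = NULL) {
  stopifnot(inherits(params, "normalization_params"))
  if (is.null(phases)) {
    if (n_traces < 1) stop_invalid("'n_traces' must be >= 1")
    phases <- with_seed(seed, stats::runif(n_traces, 0, 2 * pi))
  }
  n_traces <- length(phases)
  offs <- column_offsets(params)
  center <- which.min(abs(offs))
  t <- seq(0, duration - 1 / sim_rate, by = 1 / sim_rate)
  nt <- length(t)
  # F1 projection vectors (amplitude convention: pure A*sin -> A)
  wc <- cos(2 * pi * temporal_frequency * t)
  ws <- sin(2 * pi * temporal_frequency * t)
  f1_of <- function(mat) {
    a <- 2 * crossprod(mat, wc) / nt
    b <- 2 * crossprod(mat, ws) / nt
    sqrt(a^2 + b^2)
  }
  curve <- data.frame(mean_luminance = mean_luminances,
                      F1_tm = NA_real_, F1_input = NA_real_)
  for (li in seq_along(mean_luminances)) {
    L <- mean_luminances[li]
    J <- matrix(0, nt, n_traces)
    I <- NULL
    for (ci in seq_along(offs)) {
      ph <- phases + 2 * pi * offs[ci] / spatial_wavelength
      s <- L * (1 + contrast * sin(outer(2 * pi * temporal_frequency * t, ph, "+")))
      r <- membrane_calcium_response(s, params$input_params)
      J <- J + r
      if (ci == center) I <- r
    }
    R <- I / (params$g_l + J^params$p)
    curve$F1_tm[li] <- mean(f1_of(R))
    curve$F1_input[li] <- mean(f1_of(I))
  }
  slope_tm <- luminance_slope(curve$mean_luminance, curve$F1_tm)
  slope_input <- luminance_slope(curve$mean_luminance, curve$F1_input)
  structure(list(curve = curve, slope_tm = slope_tm,
                 slope_input = slope_input, params = params,
                 contrast = contrast, n_traces = n_traces, seed = seed,
                 temporal_frequency = temporal_frequency,
                 spatial_wavelength = spatial_wavelength,
                 duration = duration, sim_rate = sim_rate),
            class = "circuit_curves")
}

#' @export
print.circuit_curves <- function(x, ...) {
  cat(sprintf("Tm contrast-response curve (p = %d, pooling %g deg, g_l = %.4g, %d traces)\n",
              x$params$p, x$params$pooling_diameter, x$params$g_l, x$n_traces))
  print(x$curve, row.names = FALSE)
  cat(sprintf("  F1 slope vs log10(luminance): Tm %.4g, un-normalized input %.4g (ratio %.3g)\n",
              x$slope_tm, x$slope_input, x$slope_tm / x$slope_input))
  invisible(x)
}

#' @export
plot.circuit_curves <- function(x, ...) {
  graphics::plot(x$curve$mean_luminance, x$curve$F1_tm, log = "x", type = "b",
                 xlab = "mean luminance", ylab = "F1 amplitude", ...)
  invisible(x)
}

#' Calibrate the leak conductance of the linear normalization model
#'
#' One-dimensional search (golden-section on log g_l) for the leak conductance
#' that minimizes the magnitude of the p = 1 model's F1-versus-log-luminance
#' slope at the given pooling extent, i.e. the maximally luminance-invariant
#' linear circuit. The published model does not report g_l; this calibration
#' defines the package default.
#'
#' @param pooling_diameter Pooling extent, degrees.
#' @param input_params [membrane_params()] of the columnar input.
#' @param n_traces Traces per luminance during calibration.
#' @param seed Integer seed (fixed phase draws across candidate g_l values).
#' @param interval Search interval for g_l.
#' @param ... Passed to [simulate_contrast_curves()].
#' @return List with `g_l` (the calibrated value) and `slope` (the attained
#'   slope magnitude).
#' @export
calibrate_leak_conductance <- function(pooling_diameter = 15,
                                       input_params = membrane_params(),
                                       n_traces = 200, seed = 1L,
                                       interval = c(0.01, 100), ...) {
  phases <- with_seed(seed, stats::runif(n_traces, 0, 2 * pi))
  objective <- function(log_gl) {
    p <- normalization_params(g_l = exp(log_gl), p = 1,
                              pooling_diameter = pooling_diameter,
                              input_params = input_params)
    abs(simulate_contrast_curves(p, phases = phases, ...)$slope_tm)
  }
  opt <- stats::optimize(objective, log(interval))
  list(g_l = exp(opt$minimum), slope = opt$objective)
}
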