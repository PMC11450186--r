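# Visual stimulus generation: drifting sinusoidal gratings, moving OFF edges,
# and ternary white noise, rendered as luminance movies on a model screen.
#
# Luminance convention: movie frames are in normalized units L / I_max in
# [0, 1]; the physical maximum luminance (in 1e4 photons s^-1 photoreceptor^-1)
# travels along as `i_max` metadata and is used by the model stages to convert
# normalized movies into the units the membrane parameters were fitted in.

#' Screen geometry for stimulus rendering
#'
#' Defines the pixel raster stimuli are rendered on. Coordinates are degrees
#' of visual angle, x = azimuth and y = elevation, with the origin at the
#' screen center and pixel centers offset half a pixel from the screen edge.
#'
#' @param extent_deg Screen extent in degrees, `c(width, height)`.
#' @param degrees_per_pixel Angular pixel size in degrees.
#' @param frame_rate Display frame rate in Hz.
#' @return An object of class `screen_geometry` with pixel center coordinates.
#' @examples
#' scr <- screen_geometry(c(60, 60), degrees_per_pixel = 0.5)
#' range(scr$x)
#' @export
screen_geometry <- function(extent_deg = c(60, 60), degrees_per_pixel = 0.5,
                            frame_rate = 100) {
  check_number(degrees_per_pixel, "degrees_per_pixel", lower = 1e-6)
  check_number(frame_rate, "frame_rate", lower = 1e-6)
  if (length(extent_deg) == 1L) extent_deg <- rep(extent_deg, 2L)
  nx <- round(extent_deg[1] / degrees_per_pixel)
  ny <- round(extent_deg[2] / degrees_per_pixel)
  if (nx < 1 || ny < 1) stop_invalid("screen extent smaller than one pixel")
  x <- (seq_len(nx) - (nx + 1) / 2) * degrees_per_pixel
  y <- (seq_len(ny) - (ny + 1) / 2) * degrees_per_pixel
  structure(list(extent_deg = c(nx, ny) * degrees_per_pixel,
                 degrees_per_pixel = degrees_per_pixel,
                 frame_rate = frame_rate, x = x, y = y, nx = nx, ny = ny),
            class = "screen_geometry")
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("Screen: %.4g x %.4g deg, %.3g deg/px (%d x %d px), %g Hz\n",
              x$extent_deg[1], x$extent_deg[2], x$degrees_per_pixel,
              x$nx, x$ny, x$frame_rate))
  invisible(x)
}

#' Stimulus movie container
#'
#' A luminance movie: a time x elevation x azimuth array in normalized
#' luminance units, with frame rate, angular resolution and per-frame epoch
#' labels. This is the common currency between stimulus generation, circuit
#' models and the imaging-analysis pipeline.
#'
#' @param frames Numeric array `[time, y, x]`, all values >= 0.
#' @param frame_rate Frames per second.
#' @param degrees_per_pixel Angular pixel size in degrees.
#' @param epoch_labels Character vector, one label per frame.
#' @param seed Seed the movie was generated from (or `NA`).
#' @param i_max Physical maximum luminance metadata, in
#'   1e4 photons s^-1 photoreceptor^-1 (default 21.7).
#' @return An object of class `stimulus_movie`.
#' @export
stimulus_movie <- function(frames, frame_rate, degrees_per_pixel,
                           epoch_labels = NULL, seed = NA_integer_,
                           i_max = 21.7) {
  if (length(dim(frames)) != 3L) stop_invalid("'frames' must be a 3-D array [time, y, x]")
  if (any(!is.finite(frames)) || any(frames < 0)) {
    stop_invalid("luminance frames must be finite and non-negative")
  }
  if (is.null(epoch_labels)) epoch_labels <- rep("stimulus", dim(frames)[1])
  if (length(epoch_labels) != dim(frames)[1]) {
    stop_invalid("'epoch_labels' must have one entry per frame")
  }
  structure(list(frames = frames, frame_rate = frame_rate,
                 degrees_per_pixel = degrees_per_pixel,
                 epoch_labels = as.character(epoch_labels),
                 seed = seed, i_max = i_max),
            class = "stimulus_movie")
}

#' @export
print.stimulus_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Stimulus movie: %d frames (%.3g s at %g Hz), %d x %d px (%.3g deg/px)\n",
              d[1], d[1] / x$frame_rate, x$frame_rate, d[2], d[3],
              x$degrees_per_pixel))
  cat(sprintf("  epochs: %s\n", paste(unique(x$epoch_labels), collapse = ", ")))
  cat(sprintf("  luminance range: [%.4g, %.4g] (normalized; I_max = %.4g)\n",
              min(x$frames), max(x$frames), x$i_max))
  invisible(x)
}

#' Movie frame times
#' @param movie A [stimulus_movie()].
#' @return Numeric vector of frame onset times in seconds, starting at 0.
#' @export
movie_times <- function(movie) {
  (seq_len(dim(movie$frames)[1]) - 1) / movie$frame_rate
}

## ---- apertures --------------------------------------------------------------

#' Stimulus apertures
#'
#' Apertures restrict a grating to a disc (optionally surrounded by an annulus
#' of fixed luminance); outside the aperture the epoch's mean luminance is
#' shown.
#'
#' @param diameter,inner,outer Diameters in degrees.
#' @param center Aperture center `c(x, y)` in degrees.
#' @param annulus_luminance Normalized luminance of the annulus ring.
#' @return An aperture description used by [make_drifting_grating()].
#' @export
aperture_full_field <- function() structure(list(type = "full_field"), class = "aperture")

#' @rdname aperture_full_field
#' @export
aperture_disc <- function(diameter, center = c(0, 0)) {
  check_number(diameter, "diameter", lower = 1e-9)
  structure(list(type = "disc", diameter = diameter, center = center),
            class = "aperture")
}

#' @rdname aperture_full_field
#' @export
aperture_disc_annulus <- function(inner, outer, annulus_luminance,
                                  center = c(0, 0)) {
  check_number(inner, "inner", lower = 1e-9)
  check_number(outer, "outer", lower = inner)
  check_number(annulus_luminance, "annulus_luminance", lower = 0)
  structure(list(type = "disc_with_annulus", inner = inner, outer = outer,
                 annulus_luminance = annulus_luminance, center = center),
            class = "aperture")
}

aperture_extent <- function(ap) {
  switch(ap$type,
         full_field = 0,
         disc = ap$diameter + 2 * max(abs(ap$center)),
         disc_with_annulus = ap$outer + 2 * max(abs(ap$center)))
}

## ---- grating ----------------------------------------------------------------

#' Drifting sinusoidal grating specification
#'
#' Defaults follow the standard protocol: 1 Hz temporal frequency (30 deg/s at
#' 30 deg spatial wavelength), 100% Michelson contrast, five mean luminance
#' levels (1.2, 2.6, 5.3, 7.9, 10.6 in 1e4 photons s^-1 photoreceptor^-1,
#' stored normalized by I_max), 4 s epochs interleaved with 4 s of full-field
#' mean luminance, epoch order randomized.
#'
#' @param temporal_frequency Drift temporal frequency in Hz. If `speed` is
#'   given instead, the frequency is `speed / spatial_wavelength`.
#' @param spatial_wavelength Spatial wavelength in degrees.
#' @param michelson_contrast Michelson contrast in `[0, 1]`.
#' @param mean_luminances Mean luminance of each epoch, normalized units.
#' @param epoch_duration,interleave_duration Durations in seconds.
#' @param aperture An aperture object (see [aperture_full_field()]).
#' @param direction Unit vector of drift direction `c(dx, dy)`.
#' @param randomize_epochs Randomize epoch order from `seed`?
#' @param speed Optional drift speed in deg/s (overrides `temporal_frequency`).
#' @param phase Spatial phase offset in radians added to the aligned default.
#' @param seed Integer seed for epoch randomization.
#' @param i_max Physical maximum luminance metadata.
#' @return An object of class `grating_spec`.
#' @export
grating_spec <- function(temporal_frequency = 1, spatial_wavelength = 30,
                         michelson_contrast = 1,
                         mean_luminances = c(1.2, 2.6, 5.3, 7.9, 10.6) / 21.7,
                         epoch_duration = 4, interleave_duration = 4,
                         aperture = aperture_full_field(),
                         direction = c(1, 0), randomize_epochs = TRUE,
                         speed = NULL, phase = 0, seed = 1L, i_max = 21.7) {
  if (!is.null(speed)) temporal_frequency <- speed / spatial_wavelength
  check_number(temporal_frequency, "temporal_frequency", lower = 1e-9)
  check_number(spatial_wavelength, "spatial_wavelength", lower = 1e-9)
  check_number(michelson_contrast, "michelson_contrast", lower = 0, upper = 1)
  if (any(mean_luminances < 0)) stop_invalid("mean luminances must be >= 0")
  dn <- sqrt(sum(direction^2))
  if (dn == 0) stop_invalid("'direction' must be a non-zero vector")
  structure(list(temporal_frequency = temporal_frequency,
                 spatial_wavelength = spatial_wavelength,
                 michelson_contrast = michelson_contrast,
                 mean_luminances = mean_luminances,
                 epoch_duration = epoch_duration,
                 interleave_duration = interleave_duration,
                 aperture = aperture, direction = direction / dn,
                 randomize_epochs = isTRUE(randomize_epochs),
                 phase = phase, seed = as.integer(seed), i_max = i_max),
            class = "grating_spec")
}

# Sinusoidal luminance pattern at pixel coordinates for one time point.
grating_field <- function(spec, xg, yg, t, phase0) {
  u <- xg * spec$direction[1] + yg * spec$direction[2]
  sin(2 * pi * (u / spec$spatial_wavelength - spec$temporal_frequency * t) + phase0)
}

#' Render a drifting sinusoidal grating movie
#'
#' Each mean-luminance level becomes one drifting epoch; epochs are interleaved
#' with full-field frames at the epoch's mean luminance and (optionally)
#' presented in an order randomized from the spec seed. The default spatial
#' phase is aligned so that a pixel center sits on the sine peak at epoch
#' onset, which makes the rendered modulation attain the exact nominal
#' Michelson contrast over an epoch.
#'
#' @param spec A [grating_spec()].
#' @param screen A [screen_geometry()]. Its frame rate must exceed twice the
#'   grating temporal frequency.
#' @return A [stimulus_movie()] with epoch labels `"lum=<value>"` for drifting
#'   epochs and `"interleave:lum=<value>"` for the interleaves.
#' @examples
#' scr <- screen_geometry(c(16, 16), 2, frame_rate = 40)
#' mov <- make_drifting_grating(grating_spec(epoch_duration = 1,
#'                                           interleave_duration = 0.5), scr)
#' michelson_contrast(mov$frames[mov$epoch_labels == "lum=0.2442", , ])
#' @export
make_drifting_grating <- function(spec, screen = screen_geometry()) {
  stopifnot(inherits(spec, "grating_spec"), inherits(screen, "screen_geometry"))
  if (screen$frame_rate < 2 * spec$temporal_frequency) {
    stop_invalid("frame rate %g Hz below Nyquist for a %g Hz grating",
                 screen$frame_rate, spec$temporal_frequency)
  }
  if (aperture_extent(spec$aperture) > min(screen$extent_deg)) {
    stop_invalid("aperture (%.3g deg) exceeds the screen extent (%.3g deg)",
                 aperture_extent(spec$aperture), min(screen$extent_deg))
  }
  xg <- matrix(screen$x, screen$ny, screen$nx, byrow = TRUE)
  yg <- matrix(screen$y, screen$ny, screen$nx)
  # align the first pixel (along the drift axis) with the sine peak at t = 0
  u0 <- min(xg * spec$direction[1] + yg * spec$direction[2])
  phase0 <- pi / 2 - 2 * pi * u0 / spec$spatial_wavelength + spec$phase

  order_idx <- seq_along(spec$mean_luminances)
  if (spec$randomize_epochs && length(order_idx) > 1L) {
    order_idx <- with_seed(spec$seed, sample(order_idx))
  }
  n_ep <- max(1L, round(spec$epoch_duration * screen$frame_rate))
  n_il <- round(spec$interleave_duration * screen$frame_rate)
  t_ep <- (seq_len(n_ep) - 1) / screen$frame_rate

  mask <- aperture_mask(spec$aperture, xg, yg)
  frames_list <- list(); labels <- character(0)
  for (i in order_idx) {
    lum <- spec$mean_luminances[i]
    lab <- sprintf("lum=%.4g", lum)
    ep <- array(0, dim = c(n_ep, screen$ny, screen$nx))
    for (k in seq_len(n_ep)) {
      g <- lum * (1 + spec$michelson_contrast * grating_field(spec, xg, yg, t_ep[k], phase0))
      bg <- matrix(lum, screen$ny, screen$nx)
      if (!is.null(mask$annulus)) bg[mask$annulus] <- spec$aperture$annulus_luminance
      g[!mask$inside] <- bg[!mask$inside]
      ep[k, , ] <- g
    }
    frames_list <- c(frames_list, list(ep))
    labels <- c(labels, rep(lab, n_ep))
    if (n_il > 0) {
      il <- array(lum, dim = c(n_il, screen$ny, screen$nx))
      frames_list <- c(frames_list, list(il))
      labels <- c(labels, rep(paste0("interleave:", lab), n_il))
    }
  }
  frames <- do.call(abind_time, frames_list)
  stimulus_movie(frames, screen$frame_rate, screen$degrees_per_pixel,
                 labels, spec$seed, spec$i_max)
}

aperture_mask <- function(ap, xg, yg) {
  if (ap$type == "full_field") {
    return(list(inside = matrix(TRUE, nrow(xg), ncol(xg)), annulus = NULL))
  }
  r2 <- (xg - ap$center[1])^2 + (yg - ap$center[2])^2
  if (ap$type == "disc") {
    list(inside = r2 <= (ap$diameter / 2)^2, annulus = NULL)
  } else {
    inside <- r2 <= (ap$inner / 2)^2
    annulus <- r2 > (ap$inner / 2)^2 & r2 <= (ap$outer / 2)^2
    list(inside = inside, annulus = annulus)
  }
}

# Bind arrays along the time (first) dimension.
abind_time <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  total <- sum(vapply(parts, function(p) dim(p)[1], numeric(1)))
  out <- array(0, dim = c(total, d[2], d[3]))
  at <- 0L
  for (p in parts) {
    n <- dim(p)[1]
    out[at + seq_len(n), , ] <- p
    at <- at + n
  }
  out
}

## ---- OFF edge ---------------------------------------------------------------

#' Moving OFF edge specification
#'
#' A 1 s full-field presentation of a background luminance followed by a dark
#' edge sweeping across the screen at constant speed and Weber contrast
#' (default -100%). Epochs are randomized and separated by full darkness.
#'
#' @param background_luminances Background luminances (normalized), all > 0.
#'   Defaults to the protocol's six levels in units of I_max = 21.7.
#' @param edge_speed Edge speed in deg/s.
#' @param weber_contrast Weber contrast `(I_edge - I_background)/I_background`.
#' @param pre_duration Full-field duration before the edge, seconds.
#' @param inter_epoch_dark Dark interval between epochs, seconds.
#' @param seed Integer seed for epoch randomization.
#' @param i_max Physical maximum luminance metadata.
#' @return An object of class `edge_spec`.
#' @export
edge_spec <- function(background_luminances = c(1.2, 2.6, 5.3, 10.6, 16, 21.4) / 21.7,
                      edge_speed = 30, weber_contrast = -1, pre_duration = 1,
                      inter_epoch_dark = 4, seed = 1L, i_max = 21.7) {
  if (any(background_luminances <= 0)) {
    stop_invalid("background luminances must be > 0 (Weber contrast is relative to background)")
  }
  check_number(edge_speed, "edge_speed", lower = 1e-9)
  check_number(weber_contrast, "weber_contrast", lower = -1)
  structure(list(background_luminances = background_luminances,
                 edge_speed = edge_speed, weber_contrast = weber_contrast,
                 pre_duration = pre_duration, inter_epoch_dark = inter_epoch_dark,
                 seed = as.integer(seed), i_max = i_max),
            class = "edge_spec")
}

#' Render a moving OFF-edge movie
#'
#' @param spec An [edge_spec()].
#' @param screen A [screen_geometry()].
#' @return A [stimulus_movie()]; edge epochs are labelled `"edge:lum=<value>"`,
#'   the preceding full-field second `"pre:lum=<value>"` and the dark
#'   interleaves `"dark"`.
#' @export
make_off_edge <- function(spec, screen = screen_geometry()) {
  stopifnot(inherits(spec, "edge_spec"), inherits(screen, "screen_geometry"))
  order_idx <- seq_along(spec$background_luminances)
  if (length(order_idx) > 1L) order_idx <- with_seed(spec$seed, sample(order_idx))
  fr <- screen$frame_rate
  n_pre <- round(spec$pre_duration * fr)
  t_sweep <- screen$extent_deg[1] / spec$edge_speed
  n_sweep <- ceiling(t_sweep * fr)
  n_dark <- round(spec$inter_epoch_dark * fr)
  x0 <- min(screen$x) - screen$degrees_per_pixel / 2  # screen left border

  frames_list <- list(); labels <- character(0)
  for (i in order_idx) {
    lum <- spec$background_luminances[i]
    lum_edge <- lum * (1 + spec$weber_contrast)
    lab <- sprintf("lum=%.4g", lum)
    pre <- array(lum, dim = c(n_pre, screen$ny, screen$nx))
    sweep <- array(lum, dim = c(n_sweep, screen$ny, screen$nx))
    for (k in seq_len(n_sweep)) {
      front <- x0 + spec$edge_speed * (k - 1) / fr
      covered <- screen$x <= front
      if (any(covered)) sweep[k, , covered] <- lum_edge
    }
    dark <- array(0, dim = c(n_dark, screen$ny, screen$nx))
    frames_list <- c(frames_list, list(pre, sweep, dark))
    labels <- c(labels, rep(paste0("pre:", lab), n_pre),
                rep(paste0("edge:", lab), n_sweep), rep("dark", n_dark))
  }
  frames <- do.call(abind_time, frames_list)
  stimulus_movie(frames, fr, screen$degrees_per_pixel, labels,
                 spec$seed, spec$i_max)
}

## ---- ternary noise ----------------------------------------------------------

#' Ternary white-noise specification
#'
#' Checkerboard squares (2.5 deg) or vertical stripes (5 deg) independently
#' take one of three luminance levels -- darkness, 0.5 I_max, I_max -- with
#' equal probability at each 20 Hz update. A 4 s full-field prelude at the
#' intermediate level precedes the noise.
#'
#' @param element `"square"` (2.5 deg) or `"stripe"` (5 deg wide).
#' @param element_size Element size in degrees (default per element type).
#' @param update_rate Update rate in Hz.
#' @param duration Noise duration in seconds (excluding the prelude).
#' @param baseline_prelude Prelude duration in seconds.
#' @param seed Integer seed.
#' @param i_max Physical maximum luminance metadata.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(element = c("square", "stripe"), element_size = NULL,
                       update_rate = 20, duration = 180, baseline_prelude = 4,
                       seed = 1L, i_max = 21.7) {
  element <- match.arg(element)
  if (is.null(element_size)) element_size <- if (element == "square") 2.5 else 5
  check_number(element_size, "element_size", lower = 1e-9)
  check_number(update_rate, "update_rate", lower = 1e-9)
  if (duration < 1 / update_rate) {
    stop_invalid("noise duration (%g s) shorter than one update interval", duration)
  }
  structure(list(element = element, element_size = element_size,
                 update_rate = update_rate, duration = duration,
                 baseline_prelude = baseline_prelude, seed = as.integer(seed),
                 i_max = i_max),
            class = "noise_spec")
}

#' Render a ternary white-noise movie
#'
#' The movie is generated at the noise update rate, one pixel per noise
#' element (`degrees_per_pixel` = element size); element counts are snapped to
#' whole elements with a warning when snapping changes the size by more than
#' 5%. Levels are `{0, 0.5, 1}` in normalized units with equal probability.
#'
#' @param spec A [noise_spec()].
#' @param screen A [screen_geometry()] (its extent defines the covered area).
#' @return A [stimulus_movie()] with epoch labels `"prelude"` and `"noise"`.
#' @export
make_ternary_noise <- function(spec, screen = screen_geometry()) {
  stopifnot(inherits(spec, "noise_spec"), inherits(screen, "screen_geometry"))
  nx <- max(1L, round(screen$extent_deg[1] / spec$element_size))
  eff <- screen$extent_deg[1] / nx
  if (abs(eff - spec$element_size) / spec$element_size > 0.05) {
    warning(sprintf("element size snapped from %.3g to %.3g deg", spec$element_size, eff))
  }
  ny <- if (spec$element == "stripe") 1L else max(1L, round(screen$extent_deg[2] / spec$element_size))
  n_noise <- round(spec$duration * spec$update_rate)
  n_pre <- round(spec$baseline_prelude * spec$update_rate)
  levels <- c(0, 0.5, 1)
  draws <- with_seed(spec$seed,
                     sample(levels, n_noise * ny * nx, replace = TRUE))
  frames <- array(0.5, dim = c(n_pre + n_noise, ny, nx))
  frames[n_pre + seq_len(n_noise), , ] <- array(draws, dim = c(n_noise, ny, nx))
  labels <- c(rep("prelude", n_pre), rep("noise", n_noise))
  stimulus_movie(frames, spec$update_rate, eff, labels, spec$seed, spec$i_max)
}

## ---- contrast metrics -------------------------------------------------------

#' Michelson contrast of a luminance pattern
#'
#' `(max - min) / (max + min)` over the supplied frames (one spatial period or
#' more of a periodic pattern).
#'
#' @param frames Numeric array or vector of luminances, all >= 0.
#' @return Michelson contrast as a fraction in `[0, 1]`.
#' @export
michelson_contrast <- function(frames) {
  if (any(frames < 0)) stop_invalid("luminances must be >= 0")
  mx <- max(frames); mn <- min(frames)
  if (mx + mn == 0) stop_invalid("contrast undefined for an all-zero field")
  (mx - mn) / (mx + mn)
}

#' Weber contrast of an object against its background
#'
#' `(I_edge - I_background) / I_background`.
#'
#' @param i_edge Object (edge) luminance.
#' @param i_background Background luminance, > 0.
#' @return Weber contrast as a fraction.
#' @export
weber_contrast <- function(i_edge, i_background) {
  if (any(i_background <= 0)) {
    stop_invalid("Weber contrast undefined for background luminance <= 0")
  }
  (i_edge - i_background) / i_background
}
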