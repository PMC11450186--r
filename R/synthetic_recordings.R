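# Ground-truth synthetic ROI recordings: linear-nonlinear neurons with known
# Gaussian receptive fields, known luminance-gain laws, GCaMP-like temporal
# kernels and trial structure, so the analysis pipeline can be validated
# end-to-end without any real data.

#' Ground-truth synthetic neuron
#'
#' @param rf_center Receptive-field center `c(x, y)` in degrees.
#' @param rf_sigma Gaussian RF standard deviation, degrees (> 0).
#' @param gain_law One of `"luminance_scaling"` (lamina-neuron-like responses
#'   growing with background luminance), `"luminance_invariant"` (Tm1-like:
#'   drive divided by the pooled luminance) or `"low_luminance_enhancing"`
#'   (Tm9-like: drive divided by the squared pooled luminance).
#' @param polarity `"OFF"` or `"ON"` (sign of the contrast drive).
#' @param noise_sd Additive Gaussian noise, as a fraction of the response
#'   standard deviation (>= 0).
#' @param temporal_kernel `NULL` for the default biexponential
#'   calcium-indicator kernel (50 ms rise, 400 ms decay), `"delta"` for an
#'   instantaneous response, or a numeric kernel sampled at the movie frame
#'   rate.
#' @param g0 Leak constant of the divisive gain laws (model luminance units).
#' @return An object of class `ground_truth_neuron`.
#' @export
ground_truth_neuron <- function(rf_center = c(0, 0), rf_sigma = 4,
                                gain_law = c("luminance_scaling",
                                             "luminance_invariant",
                                             "low_luminance_enhancing"),
                                polarity = c("OFF", "ON"), noise_sd = 0.1,
                                temporal_kernel = NULL, g0 = 0.05) {
  gain_law <- match.arg(gain_law)
  polarity <- match.arg(polarity)
  check_number(rf_sigma, "rf_sigma", lower = 1e-9)
  check_number(noise_sd, "noise_sd", lower = 0)
  structure(list(rf_center = rf_center, rf_sigma = rf_sigma,
                 gain_law = gain_law, polarity = polarity,
                 noise_sd = noise_sd, temporal_kernel = temporal_kernel,
                 g0 = g0),
            class = "ground_truth_neuron")
}

#' Recording manifest
#'
#' @param neurons List of [ground_truth_neuron()]s.
#' @param frame_rate Imaging frame rate in Hz; two-photon recordings run at
#'   10-15 Hz, and rates outside that range trigger a warning.
#' @param n_trials Number of identical-stimulus trials.
#' @param seed Integer seed; recordings are bit-reproducible from it.
#' @return An object of class `recording_manifest`.
#' @export
recording_manifest <- function(neurons, frame_rate = 12, n_trials = 3,
                               seed = 1L) {
  if (inherits(neurons, "ground_truth_neuron")) neurons <- list(neurons)
  stopifnot(all(vapply(neurons, inherits, logical(1), "ground_truth_neuron")))
  check_number(frame_rate, "frame_rate", lower = 1e-9)
  if (frame_rate < 10 || frame_rate > 15) {
    warning("frame_rate outside the usual 10-15 Hz imaging range")
  }
  structure(list(neurons = neurons, frame_rate = frame_rate,
                 n_trials = as.integer(n_trials), seed = as.integer(seed)),
            class = "recording_manifest")
}

biexp_kernel <- function(rate, rise = 0.05, decay = 0.4) {
  t <- seq(0, 5 * decay, by = 1 / rate)
  k <- (1 - exp(-t / rise)) * exp(-t / decay)
  k / sum(k)
}

#' Generate a synthetic ROI recording
#'
#' For each neuron: the movie is weighted by the neuron's normalized Gaussian
#' receptive field; the contrast drive is the (polarity-signed) deviation of
#' the pooled luminance from its global mean; the gain law is applied against
#' the epoch-wise mean pooled luminance in model units (dividing by it, by
#' its square, or not at all); the result is convolved with the temporal
#' kernel, a fluorescence offset is added, the trace is resampled to the
#' imaging frame rate, and i.i.d. Gaussian noise is drawn per trial. A
#' ground-truth sidecar records every ingredient.
#'
#' @param manifest A [recording_manifest()].
#' @param movie A [stimulus_movie()] covering all RF centers.
#' @param f_offset Baseline fluorescence added to all traces (keeps dF/F
#'   baselines positive).
#' @return An object of class `roi_recording`: `traces` (array
#'   `[roi, time, trial]`), `frame_rate`, `times`, `epoch_labels` (resampled),
#'   and `ground_truth` (the manifest plus each neuron's noiseless response).
#' @export
generate_recording <- function(manifest, movie, f_offset = 1) {
  stopifnot(inherits(manifest, "recording_manifest"),
            inherits(movie, "stimulus_movie"))
  d <- dim(movie$frames)
  xs <- (seq_len(d[3]) - (d[3] + 1) / 2) * movie$degrees_per_pixel
  ys <- (seq_len(d[2]) - (d[2] + 1) / 2) * movie$degrees_per_pixel
  t_stim <- movie_times(movie)
  nf <- floor(t_stim[length(t_stim)] * manifest$frame_rate) + 1L
  t_img <- (seq_len(nf) - 1) / manifest$frame_rate
  epoch_img <- movie$epoch_labels[pmin(d[1], floor(t_img * movie$frame_rate) + 1L)]
  stim_flat <- matrix(movie$frames, nrow = d[1])
  n_roi <- length(manifest$neurons)
  traces <- array(0, dim = c(n_roi, nf, manifest$n_trials))
  clean <- matrix(0, n_roi, nf)
  for (i in seq_len(n_roi)) {
    nr <- manifest$neurons[[i]]
    if (nr$rf_center[1] < min(xs) || nr$rf_center[1] > max(xs) ||
        nr$rf_center[2] < min(ys) || nr$rf_center[2] > max(ys)) {
      stop_invalid("RF center (%g, %g) outside the movie extent",
                   nr$rf_center[1], nr$rf_center[2])
    }
    wx <- exp(-(xs - nr$rf_center[1])^2 / (2 * nr$rf_sigma^2))
    wy <- exp(-(ys - nr$rf_center[2])^2 / (2 * nr$rf_sigma^2))
    w <- as.numeric(outer(wy, wx))
    w <- w / sum(w)
    lum <- as.numeric(stim_flat %*% w)             # pooled luminance, normalized
    drive <- lum - mean(lum)
    if (nr$polarity == "OFF") drive <- -drive
    pool <- stats::ave(lum, movie$epoch_labels) * movie$i_max  # model units
    r <- switch(nr$gain_law,
                luminance_scaling = drive * movie$i_max,
                luminance_invariant = drive * movie$i_max / (nr$g0 + pool),
                low_luminance_enhancing = drive * movie$i_max / (nr$g0 + pool)^2)
    ker <- nr$temporal_kernel
    if (is.null(ker)) ker <- biexp_kernel(movie$frame_rate)
    if (!identical(ker, "delta")) {
      r <- stats::filter(c(rep(0, length(ker) - 1), r), rev(ker),
                         sides = 1)[length(ker) - 1 + seq_along(r)]
    }
    r_img <- stats::approx(t_stim, r, xout = t_img, rule = 2)$y
    clean[i, ] <- r_img + f_offset
  }
  with_seed(manifest$seed, {
    for (tr in seq_len(manifest$n_trials)) {
      for (i in seq_len(n_roi)) {
        sdn <- manifest$neurons[[i]]$noise_sd * stats::sd(clean[i, ])
        traces[i, , tr] <- clean[i, ] + stats::rnorm(nf, sd = sdn)
      }
    }
  })
  structure(list(traces = traces, frame_rate = manifest$frame_rate,
                 times = t_img, epoch_labels = epoch_img,
                 ground_truth = list(manifest = manifest, clean = clean,
                                     f_offset = f_offset,
                                     movie_seed = movie$seed)),
            class = "roi_recording")
}

#' @export
print.roi_recording <- function(x, ...) {
  d <- dim(x$traces)
  cat(sprintf("Synthetic recording: %d ROIs x %d frames (%g Hz) x %d trials\n",
              d[1], d[2], x$frame_rate, d[3]))
  invisible(x)
}
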