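# Imaging analysis: dF/F, reliability, F1, slopes, edges, heatmaps, STRFs.

test_that("dF/F normalizes against trace or prelude baselines", {
  expect_equal(dff(c(1, 3)), c(-0.5, 0.5))
  expect_equal(dff(rep(5, 10)), rep(0, 10))
  m <- rbind(a = c(1, 3), b = c(2, 6))
  expect_equal(dff(m), rbind(a = c(-0.5, 0.5), b = c(-0.5, 0.5)))
  # prelude baseline: first 4 s at 1 Hz -> mean 2; later value 3 -> 0.5
  tr <- c(2, 2, 2, 2, 3, 1)
  expect_equal(dff(tr, "prelude_mean", frame_rate = 1)[5], 0.5)
  expect_error(dff(c(-1, 1)), "ROI")
  expect_lt(abs(mean(dff(runif(100) + 1))), 1e-12)
})

test_that("trial reliability averages pairwise correlations against 0.6", {
  ident <- matrix(rep(sin(1:50), 3), 3, byrow = TRUE)
  r <- roi_reliability(ident)
  expect_equal(r$reliability, 1)
  expect_true(r$keep)
  neg <- rbind(sin(1:50), -sin(1:50))
  r2 <- roi_reliability(neg)
  expect_equal(r2$reliability, -1)
  expect_false(r2$keep)
  # exact pairwise correlations {0.9, 0.6, 0.3} -> mean 0.6, kept
  R <- matrix(c(1, 0.9, 0.6, 0.9, 1, 0.3, 0.6, 0.3, 1), 3)
  set.seed(6)
  trials <- trials_with_correlations(R)
  r3 <- roi_reliability(trials)
  expect_equal(r3$reliability, 0.6, tolerance = 1e-9)
  expect_true(r3$keep)
  flat <- rbind(rep(1, 20), sin(1:20))
  r4 <- roi_reliability(flat)
  expect_false(r4$defined)
  expect_false(r4$keep)
  expect_error(roi_reliability(matrix(1, 1, 10)), "2 trials")
})

test_that("F1 amplitude recovers single tones and rejects bad frequencies", {
  t <- seq(0, 4 - 0.1, by = 0.1)
  expect_equal(f1_amplitude(2 * sin(2 * pi * t), 1, 10), 2, tolerance = 1e-9)
  expect_equal(f1_amplitude(rep(3, 40), 1, 10), 0, tolerance = 1e-12)
  two_tone <- 1.5 * sin(2 * pi * t) + 0.7 * sin(2 * pi * 3 * t)
  expect_equal(f1_amplitude(two_tone, 1, 10), 1.5, tolerance = 1e-9)
  # linear in amplitude, invariant to phase
  for (phi in c(0, 0.7, 2.1)) {
    expect_equal(f1_amplitude(5 * sin(2 * pi * t + phi), 1, 10), 5,
                 tolerance = 1e-9)
  }
  expect_error(f1_amplitude(sin(t), 6, 10), "Nyquist")
  expect_error(f1_amplitude(sin(2 * pi * t[1:12]), 1, 10), "2 stimulus periods")
})

test_that("luminance slope is the OLS slope against log10 luminance", {
  L <- c(1.2, 2.6, 5.3, 7.9, 10.6)
  expect_equal(luminance_slope(L, 0.2 * log10(L) + 1), 0.2, tolerance = 1e-12)
  expect_equal(luminance_slope(L, rep(2, 5)), 0)
  set.seed(8)
  y <- 0.7 * log10(L) + rnorm(5, sd = 0.1)
  expect_equal(luminance_slope(L, y), ols_slope(log10(L), y), tolerance = 1e-12)
  expect_error(luminance_slope(c(5, 5), c(1, 2)), "distinct")
  expect_error(luminance_slope(c(-1, 2), c(1, 2)), "> 0")
})

test_that("edge responses subtract the preceding-second baseline from the peak", {
  fr <- 10
  tr <- c(rep(1, 10), c(1.2, 2, 3, 2, 1.4), rep(1, 5))
  expect_equal(edge_response(tr, fr, edge_onset = 1, edge_duration = 0.5), 2)
  expect_equal(edge_response(rep(2, 30), fr, 1, 0.5), 0)
  expect_error(edge_response(tr, fr, 1.8, 5), "outside")
})

test_that("contrast-luminance maps zoom 5x with exact bilinear ramps", {
  g <- outer(1:5, 1:5, function(i, j) 2 * i + 3 * j)
  m <- contrast_luminance_map(g)
  expect_equal(dim(m$interpolated), c(25, 25))
  # order-1 interpolation reproduces a linear ramp exactly
  ri <- seq(1, 5, length.out = 25)
  expect_equal(m$interpolated, outer(ri, ri, function(i, j) 2 * i + 3 * j),
               tolerance = 1e-12)
  expect_length(m$levels, 8)
  expect_false(m$degenerate)
  expect_equal(diff(m$levels), rep(diff(m$levels)[1], 7), tolerance = 1e-12)
  flat <- contrast_luminance_map(matrix(1, 5, 5))
  expect_true(flat$degenerate)
  expect_equal(flat$smoothed, matrix(1, 25, 25), tolerance = 1e-12)
  expect_error(contrast_luminance_map(matrix(c(1, NA, 1, 1), 2)), "complete")
})

test_that("reverse correlation recovers an instantaneous spatial filter", {
  mov <- make_ternary_noise(noise_spec(element = "stripe", duration = 180, seed = 2),
                            screen_geometry(c(60, 60), 0.5))
  xs <- (seq_len(12) - 6.5) * 5
  w <- exp(-(xs - 5)^2 / (2 * 6^2))
  s <- matrix(2 * mov$frames - 1, nrow = dim(mov$frames)[1])
  r <- 1 + 0.05 * as.numeric(s %*% w)   # fluorescence with positive baseline
  strf <- compute_strf(r, mov, trace_rate = 20)
  expect_equal(dim(strf$kernel), c(40, 12))
  expect_gt(cor(strf$kernel[1, ], w), 0.95)
  # lag-0 dominates for an instantaneous response
  expect_equal(which.max(apply(abs(strf$kernel), 1, max)), 1)
  expect_error(compute_strf(r[1:10], mov, 20), "window")
})

test_that("kernel lag structure is shift-equivariant in the response delay", {
  mov <- make_ternary_noise(noise_spec(element = "stripe", duration = 120, seed = 3),
                            screen_geometry(c(60, 60), 0.5))
  xs <- (seq_len(12) - 6.5) * 5
  w <- exp(-xs^2 / (2 * 5^2))
  s <- matrix(2 * mov$frames - 1, nrow = dim(mov$frames)[1])
  r0 <- as.numeric(s %*% w)
  for (k in c(2, 5)) {
    r_shift <- 1 + 0.05 * c(rep(0, k), r0[seq_len(length(r0) - k)])
    strf <- compute_strf(r_shift, mov, trace_rate = 20)
    peak_lag <- which.max(apply(abs(strf$kernel), 1, max))
    expect_equal(peak_lag, 1 + k)
  }
})

test_that("a stimulus-independent response yields a null kernel", {
  mov <- make_ternary_noise(noise_spec(element = "stripe", duration = 60, seed = 4),
                            screen_geometry(c(60, 60), 0.5))
  strf <- compute_strf(rep(2, 1280), mov, trace_rate = 20)
  expect_true(all(strf$kernel == 0))
})

test_that("kernel error shrinks roughly with the square root of data length", {
  run_err <- function(dur, seed) {
    mov <- make_ternary_noise(noise_spec(element = "stripe", duration = dur,
                                         seed = seed),
                              screen_geometry(c(60, 60), 0.5))
    xs <- (seq_len(12) - 6.5) * 5
    w <- exp(-xs^2 / (2 * 6^2))
    s <- matrix(2 * mov$frames - 1, nrow = dim(mov$frames)[1])
    set.seed(seed + 100)
    r <- 1 + 0.05 * as.numeric(s %*% w) + rnorm(nrow(s), sd = 0.2)
    strf <- compute_strf(r, mov, trace_rate = 20)
    k0 <- strf$kernel[1, ]
    a <- sum(k0 * w) / sum(k0^2)  # estimator is defined up to a free scale
    sqrt(mean((a * k0 - w)^2))
  }
  errs_short <- mean(vapply(1:4, function(s) run_err(60, s), numeric(1)))
  errs_long <- mean(vapply(1:4, function(s) run_err(240, s), numeric(1)))
  expect_gt(errs_short / errs_long, 2 * 0.7)
  expect_lt(errs_short / errs_long, 2 * 1.3)
})

test_that("STRF filtering applies amplitude and SNR thresholds", {
  mk <- function(amp, flat = 0.0001) {
    k <- matrix(flat, 40, 12)
    k[5, 6] <- -amp
    synthetic_strf(k)
  }
  keep <- filter_strfs(list(mk(0.004), mk(0.006)))
  expect_length(keep, 1)
  expect_equal(keep[[1]]$amplitude, 0.006)
  expect_length(attr(keep, "rejected"), 1)
  # low-SNR mode: amplitude 0.004 with SNR >= 10 is kept
  cand <- mk(0.004)
  expect_gt(cand$snr, 10)
  expect_length(filter_strfs(list(cand), mode = "low_snr"), 1)
  noisy <- synthetic_strf(matrix(0.0035, 40, 12))  # SNR = 1
  expect_length(filter_strfs(list(noisy), mode = "low_snr"), 0)
})

test_that("filters split a separable STRF into its factors with a Gaussian width", {
  dt <- 0.05; dx <- 5
  xs <- (seq_len(13) - 7) * dx
  lags <- (0:39) * dt
  wt <- -(lags / 0.2) * exp(1 - lags / 0.2)      # negative (OFF) temporal filter
  g <- exp(-(xs - 5)^2 / (2 * 4.25^2))
  strf <- synthetic_strf(outer(wt, g), dt = dt, dx = dx)
  fl <- extract_filters(strf)
  expect_gt(abs(cor(fl$temporal$value, wt)), 0.999)
  expect_gt(abs(cor(fl$spatial$value, g)), 0.999)
  expect_equal(fl$fit$mu, 5, tolerance = 0.05)
  expect_equal(fl$fwhm, 2.355 * 4.25, tolerance = 0.05)
  expect_equal(fl$fit$fwhm / fl$fit$sigma, 2 * sqrt(2 * log(2)), tolerance = 1e-9)
})

test_that("2-D Gaussian RF mapping recovers centers exactly and under noise", {
  xs <- seq(-20, 20, by = 2.5)
  ys <- seq(-15, 15, by = 2.5)
  f2 <- function(h, cx, cy, wx, wy) {
    outer(ys, xs, function(y, x) h * exp(-(((cx - x) / wx)^2 + ((cy - y) / wy)^2) / 2))
  }
  z <- f2(-1, 10, -5, 4, 5)
  fit <- map_rf_center(z, x_deg = xs, y_deg = ys)
  expect_lt(abs(fit$center_x - 10), 0.1)
  expect_lt(abs(fit$center_y + 5), 0.1)
  # symmetric input: center at the symmetry point
  fit0 <- map_rf_center(f2(1, 0, 0, 6, 6), x_deg = xs, y_deg = ys)
  expect_lt(abs(fit0$center_x), 1e-6)
  expect_lt(abs(fit0$center_y), 1e-6)
  # 10% additive noise: centers within 1 degree over seeded repeats
  errs <- vapply(1:50, function(s) {
    set.seed(s)
    zn <- z + matrix(rnorm(length(z), sd = 0.1), nrow(z))
    f <- map_rf_center(zn, x_deg = xs, y_deg = ys)
    sqrt((f$center_x - 10)^2 + (f$center_y + 5)^2)
  }, numeric(1))
  expect_lt(mean(errs), 1)
})
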