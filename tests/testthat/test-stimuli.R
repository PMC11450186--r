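# Stimulus generation: gratings, OFF edges, ternary noise, contrast metrics.

# Screen whose temporal and spatial sampling are commensurate with a 1 Hz,
# 30 deg grating: 8 px per wavelength and 8 frames per period, so the sine is
# sampled on the same phase grid in every frame and extrema are hit exactly.
commensurate_screen <- function() screen_geometry(c(60, 7.5), 3.75, frame_rate = 8)

test_that("drifting grating attains the requested modulation exactly", {
  for (C in c(1, 0.5, 0)) {
    spec <- grating_spec(michelson_contrast = C, mean_luminances = c(0.5, 0.25),
                         epoch_duration = 1, interleave_duration = 0,
                         randomize_epochs = FALSE)
    mov <- make_drifting_grating(spec, commensurate_screen())
    for (lum in spec$mean_luminances) {
      ep <- mov$frames[mov$epoch_labels == sprintf("lum=%.4g", lum), , ]
      expect_equal(max(ep), lum * (1 + C), tolerance = 1e-9)
      expect_equal(min(ep), lum * (1 - C), tolerance = 1e-9)
      if (C > 0) {
        expect_equal(michelson_contrast(ep), C, tolerance = 1e-6)
      } else {
        expect_true(all(ep == lum))  # zero contrast: constant frames
      }
      # per-frame spatial extrema at full modulation (aligned sampling)
      if (C == 1) {
        expect_equal(apply(ep, 1, min), rep(0, dim(ep)[1]), tolerance = 1e-9)
        expect_equal(apply(ep, 1, max), rep(2 * lum, dim(ep)[1]), tolerance = 1e-9)
      }
    }
  }
})

test_that("temporal mean over one period recovers the epoch mean luminance", {
  spec <- grating_spec(mean_luminances = 0.4, epoch_duration = 1,
                       interleave_duration = 0, randomize_epochs = FALSE)
  mov <- make_drifting_grating(spec, commensurate_screen())
  per_pixel_mean <- apply(mov$frames, c(2, 3), mean)
  expect_equal(per_pixel_mean, matrix(0.4, dim(mov$frames)[2], dim(mov$frames)[3]),
               tolerance = 1e-6)
})

test_that("grating drifts one full cycle per second at 30 deg/s and 30 deg wavelength", {
  spec <- grating_spec(speed = 30, spatial_wavelength = 30, mean_luminances = 0.5,
                       epoch_duration = 2, interleave_duration = 0,
                       randomize_epochs = FALSE)
  expect_equal(spec$temporal_frequency, 1)
  scr <- screen_geometry(c(60, 4), 2, frame_rate = 20)
  mov <- make_drifting_grating(spec, scr)
  # after exactly one second the pattern must repeat
  expect_equal(mov$frames[1, , ], mov$frames[1 + scr$frame_rate, , ],
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(mov$frames[1, , ],
                                mov$frames[1 + scr$frame_rate %/% 2, , ])))
})

test_that("grating spec and geometry errors are raised", {
  expect_error(grating_spec(spatial_wavelength = -1), "spatial_wavelength")
  expect_error(grating_spec(michelson_contrast = 1.2), "michelson_contrast")
  expect_error(make_drifting_grating(
    grating_spec(aperture = aperture_disc(100)), screen_geometry(c(60, 60), 2)),
    "aperture")
  expect_error(make_drifting_grating(
    grating_spec(temporal_frequency = 30), screen_geometry(c(10, 10), 2, frame_rate = 20)),
    "Nyquist")
})

test_that("epoch order is a seeded permutation and reproducible", {
  spec <- grating_spec(mean_luminances = c(0.1, 0.2, 0.3, 0.4),
                       epoch_duration = 0.5, interleave_duration = 0, seed = 42)
  scr <- screen_geometry(c(12, 4), 2, frame_rate = 8)
  m1 <- make_drifting_grating(spec, scr)
  m2 <- make_drifting_grating(spec, scr)
  expect_identical(m1$epoch_labels, m2$epoch_labels)
  expect_identical(m1$frames, m2$frames)
  seen <- unique(m1$epoch_labels)
  expect_setequal(seen, sprintf("lum=%.4g", spec$mean_luminances))
})

test_that("disc and annulus apertures mask the grating as specified", {
  scr <- screen_geometry(c(40, 40), 2, frame_rate = 8)
  spec <- grating_spec(mean_luminances = 0.5, epoch_duration = 0.25,
                       interleave_duration = 0, randomize_epochs = FALSE,
                       aperture = aperture_disc_annulus(10, 30, annulus_luminance = 0.8))
  mov <- make_drifting_grating(spec, scr)
  fr <- mov$frames[1, , ]
  xg <- matrix(scr$x, scr$ny, scr$nx, byrow = TRUE)
  yg <- matrix(scr$y, scr$ny, scr$nx)
  r <- sqrt(xg^2 + yg^2)
  expect_true(all(fr[r > 5 & r <= 15] == 0.8))    # annulus ring
  expect_true(all(fr[r > 15] == 0.5))             # outside: mean luminance
  expect_gt(diff(range(fr[r <= 5])), 0.2)         # grating visible inside
})

test_that("OFF edge renders Weber contrast, traversal time and dark interleaves", {
  scr <- screen_geometry(c(60, 4), 2, frame_rate = 10)
  spec <- edge_spec(background_luminances = c(0.5, 0.25), seed = 3)
  mov <- make_off_edge(spec, scr)
  # edge region at -100% Weber contrast is fully dark
  sweep_frames <- mov$frames[mov$epoch_labels == "edge:lum=0.5", , ]
  expect_equal(min(sweep_frames), 0)
  # traversal time = 60 deg / 30 deg/s = 2 s
  expect_equal(sum(mov$epoch_labels == "edge:lum=0.5") / scr$frame_rate, 2)
  # Weber contrast recomputed from the frames matches the spec
  mid <- sweep_frames[dim(sweep_frames)[1] %/% 2, , ]
  expect_equal(weber_contrast(min(mid), 0.5), spec$weber_contrast)
  # pre-period is 1 s of uniform background, interleaves fully dark
  expect_equal(sum(mov$epoch_labels == "pre:lum=0.25") / scr$frame_rate, 1)
  expect_true(all(mov$frames[mov$epoch_labels == "dark", , ] == 0))
  expect_error(edge_spec(background_luminances = c(0.5, 0)), "background")
})

test_that("ternary noise is seed-reproducible with a mid-level prelude", {
  scr <- screen_geometry(c(60, 60), 0.5)
  sp <- noise_spec(element = "stripe", duration = 10, seed = 9)
  m1 <- make_ternary_noise(sp, scr)
  m2 <- make_ternary_noise(sp, scr)
  expect_identical(m1$frames, m2$frames)
  m3 <- make_ternary_noise(noise_spec(element = "stripe", duration = 10, seed = 10), scr)
  expect_false(identical(m1$frames, m3$frames))
  expect_true(all(m1$frames[m1$epoch_labels == "prelude", , ] == 0.5))
  expect_equal(sum(m1$epoch_labels == "prelude"), 4 * 20)
  expect_equal(m1$degrees_per_pixel, 5)
  expect_error(noise_spec(duration = 0.01), "duration")
})

test_that("ternary levels are equiprobable and independent across updates", {
  mov <- make_ternary_noise(noise_spec(element = "stripe", duration = 60, seed = 5),
                            screen_geometry(c(60, 60), 0.5))
  s <- mov$frames[mov$epoch_labels == "noise", 1, ]
  n <- length(s)
  expect_gt(n, 1e4)
  se3 <- 3 * sqrt((1 / 3) * (2 / 3) / n)
  for (lev in c(0, 0.5, 1)) {
    expect_lt(abs(mean(s == lev) - 1 / 3), se3)
  }
  # lag-1 autocorrelation of a single element's level sequence is ~0
  x <- s[, 1]
  r1 <- cor(x[-1], x[-length(x)])
  expect_lt(abs(r1), 4 / sqrt(length(x)))
})

test_that("contrast metrics follow their definitions and flag degenerate input", {
  expect_equal(michelson_contrast(c(0.2, 0.2, 0.2)), 0)
  expect_equal(michelson_contrast(c(0, 1)), 1)
  expect_equal(weber_contrast(0, 0.5), -1)
  expect_equal(weber_contrast(0.75, 0.5), 0.5)
  expect_error(michelson_contrast(rep(0, 4)), "all-zero")
  expect_error(michelson_contrast(c(-0.1, 1)), ">= 0")
  expect_error(weber_contrast(0.1, 0), "background")
})
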