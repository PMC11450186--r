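# Effective membrane/calcium model of lamina neurons and its fit.

test_that("calcium read-out follows the rectified-quadratic formula", {
  p <- membrane_params()
  expect_equal(membrane_calcium_response(0, p), 4 * 0.3^2)
  expect_equal(membrane_calcium_response(-10, p), 0)  # rectification
  s <- matrix(c(0, 2, 4, 8), 2)
  expect_equal(membrane_calcium_response(s, p),
               4 * pmax(0.3 + 0.05 * s, 0)^2)
  expect_error(membrane_params(g_inv = -1), "g_inv")
  expect_error(membrane_params(alpha = -2), "alpha")
})

test_that("scaling the stimulus and the conductance inversely cancels", {
  s <- seq(0, 10, by = 0.1)
  k <- 3.7
  r1 <- membrane_calcium_response(s, membrane_params(g_inv = 0.05))
  r2 <- membrane_calcium_response(k * s, membrane_params(g_inv = 0.05 / k))
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("F1 of the model response matches a dense quadrature oracle", {
  rate <- 1000
  t <- seq(0, 4 - 1 / rate, by = 1 / rate)
  r <- membrane_calcium_response(sin(2 * pi * t), membrane_params())
  expect_equal(f1_amplitude(r, 1, rate), quadrature_f1(r, 1, rate),
               tolerance = 1e-6)
})

test_that("explicit-Euler integration approaches the pseudo-stationary solution", {
  rate <- 2000
  t <- seq(0, 2 - 1 / rate, by = 1 / rate)
  s <- 5 * (1 + sin(2 * pi * t))
  stat <- membrane_calcium_response(s, membrane_params())
  eul <- membrane_calcium_response(s, membrane_params(), method = "euler",
                                   dt = 1 / rate, tau = 0.002)
  # away from the initial transient the fast membrane tracks the input
  idx <- t > 0.1
  expect_lt(max(abs(eul[idx] - stat[idx])) / max(stat), 0.02)
})

test_that("scene responses are pointwise, monotone, and reject bad input", {
  p <- membrane_params()
  uni <- matrix(2, 4, 5)
  expect_equal(respond_to_scene(uni, p), matrix(4 * 0.4^2, 4, 5))
  ramp <- matrix(seq(0, 10, length.out = 50), 1)
  r <- respond_to_scene(ramp, p)
  expect_true(all(diff(as.numeric(r)) >= 0))
  expect_equal(r[1, 17], 4 * max(0.3 + 0.05 * ramp[1, 17], 0)^2)
  expect_error(respond_to_scene(matrix(-1, 2, 2), p), "non-negative")
})

test_that("simulated F1 grows with mean luminance at full contrast", {
  f1 <- simulate_contrast_table(c(1.2, 2.6, 5.3, 7.9, 10.6), 1)
  expect_true(all(diff(f1) > 0))
})

test_that("membrane fit recovers planted parameters in the leak-voltage gauge", {
  lums <- c(1.2, 2.6, 5.3, 7.9, 10.6)
  tab <- expand.grid(luminance = lums, contrast = c(0.2, 0.4, 0.6, 0.8, 1))
  tab$response <- simulate_contrast_table(tab$luminance, tab$contrast)
  fit <- fit_membrane_params(tab, n_starts = 4, seed = 2)
  truth <- c(g_inv = 0.05, v_L = 0.3, alpha = 4)
  expect_lt(max(abs(coef(fit) - truth) / truth), 0.01)
  # residuals at the optimum do not exceed residuals at the generating values
  rss_true <- sum((simulate_contrast_table(tab$luminance, tab$contrast) -
                     tab$response)^2)
  expect_lte(fit$rss, rss_true + 1e-6)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(residuals(fit), tab$response - fitted(fit))
  expect_output(print(summary(fit)), "RSS")
})

test_that("membrane fit tolerates 5% response noise within 10% parameter error", {
  tab <- expand.grid(luminance = c(1.2, 2.6, 5.3, 7.9, 10.6),
                     contrast = c(0.2, 0.4, 0.6, 0.8, 1))
  tab$response <- simulate_contrast_table(tab$luminance, tab$contrast)
  noisy <- local({
    set.seed(11)
    transform(tab, response = pmax(response + rnorm(25, sd = 0.05 * sd(response)), 0))
  })
  fit <- fit_membrane_params(noisy, n_starts = 4, seed = 2)
  truth <- c(0.05, 0.3, 4)
  expect_lt(max(abs(coef(fit) - truth) / truth), 0.10)
})

test_that("degenerate fit inputs are flagged", {
  tab <- expand.grid(luminance = c(1.2, 2.6, 5.3), contrast = 1)
  tab$response <- 0
  expect_warning(fit0 <- fit_membrane_params(tab, n_starts = 2), "alpha")
  expect_lt(coef(fit0)["alpha"], 1e-6)
  one <- data.frame(luminance = 5, contrast = 1, response = 1)
  expect_error(fit_membrane_params(one), "degenerate")
  expect_warning(
    fit_membrane_params(transform(tab, response = c(0.1, 0.3, 0.5)),
                        v_L = NULL, n_starts = 2),
    "ridge")
})
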