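# Scene ensembles, trajectories, contrast distributions, Wasserstein
# distances and the pooling loss.

test_that("scene ensembles are reproducible with exact configured mean ratios", {
  e1 <- synthesize_scene_ensemble(size = 64, seed = 7)
  e2 <- synthesize_scene_ensemble(size = 64, seed = 7)
  expect_identical(e1, e2)
  e3 <- synthesize_scene_ensemble(size = 64, seed = 8)
  expect_false(identical(e1$scenes[[1]]$luminance, e3$scenes[[1]]$luminance))
  ratio <- mean(e1$scenes$sunny_a$luminance) / mean(e1$scenes$shaded_a$luminance)
  expect_equal(ratio, 4, tolerance = 1e-6)
  dims <- vapply(e1$scenes, function(s) dim(s$luminance), numeric(2))
  expect_true(all(dims == 64))
  expect_error(synthesize_scene_ensemble(size = 8), "16 px")
})

test_that("paired conditions are strongly correlated in log-luminance", {
  ens <- synthesize_scene_ensemble(seed = 1)
  co <- cor(as.numeric(log(ens$scenes$shaded_a$luminance)),
            as.numeric(log(ens$scenes$sunny_a$luminance)))
  expect_gt(co, 0.8)
})

test_that("trajectories follow the forward-wave equation in pixels", {
  scn <- scene(matrix(1, 120, 120), 0.25)
  tr <- simulate_trajectory(scn, noise_sd = 0, seed = 1)
  # z = 0: sine and drift vanish
  expect_equal(tr$T[1], 0)
  # z = nx/6: sine term at phase pi vanishes, leaving gamma * z
  z6 <- 120 / 6
  expect_equal(tr$T[z6 + 1], (1 / 3) * z6, tolerance = 1e-9)
  expect_true(all(tr$row >= 1 & tr$row <= 120))
  expect_equal(length(tr$z), 120)
})

test_that("trajectory jitter has the stated standard deviation", {
  scn <- scene(matrix(1, 5, 100000), 1)
  tr <- simulate_trajectory(scn, seed = 3)
  det <- 30 * sin(2 * pi * 3 * tr$z / 100000) + tr$z / 3
  expect_equal(sd(tr$T - det), 60, tolerance = 0.02 * 60)
})

test_that("contrast distributions keep raw samples and a unit-mass density", {
  scn <- scene(matrix(runif(64 * 64), 64), 0.5)
  resp <- respond_to_scene(scn)
  trs <- lapply(1:5, function(i) simulate_trajectory(scn, seed = i))
  cd <- sample_contrast_responses(resp, trs, "test")
  expect_length(cd$samples, 5 * 64)
  expect_equal(sum(cd$density) * diff(cd$x[1:2]), 1, tolerance = 1e-3)
  # constant response image: all samples equal, density concentrated there
  cd0 <- sample_contrast_responses(matrix(2.5, 64, 64), trs)
  expect_true(all(cd0$samples == 2.5))
  expect_lt(abs(cd0$x[which.max(cd0$density)] - 2.5), 1e-3)
  # duplicating the trajectory list duplicates samples, same moments
  cd2 <- sample_contrast_responses(resp, c(trs, trs))
  expect_equal(mean(cd2$samples), mean(cd$samples))
  expect_equal(sd(cd2$samples), sd(cd$samples), tolerance = 1e-3)
  expect_error(sample_contrast_responses(resp, list()), "trajectory")
})

test_that("KDE modes of a two-component mixture sit at the true modes", {
  x <- local({
    set.seed(4)
    c(rnorm(5000, 0, 0.05), rnorm(5000, 1, 0.05))
  })
  cd <- contrast_distribution(x)
  d <- cd$density
  peaks <- cd$x[which(diff(sign(diff(d))) == -2) + 1]
  peaks <- peaks[d[match(peaks, cd$x)] > 0.1 * max(d)]
  expect_length(peaks, 2)
  res <- diff(cd$x[1:2]) + cd$bandwidth
  expect_lt(abs(peaks[1] - 0), res)
  expect_lt(abs(peaks[2] - 1), res)
})

test_that("pooled-luminance normalization matches closed forms", {
  scn <- scene(matrix(0.8, 20, 20), 0.5)
  resp <- matrix(1.6, 20, 20)
  out <- normalize_by_pooled_luminance(resp, scn, pooling_diameter = 4, g_l = 0.05)
  expect_equal(out, matrix(1.6 / (0.05 + 0.8), 20, 20), tolerance = 1e-9)
  # one-pixel disc pools the pixel itself
  lum <- matrix(runif(400, 0.5, 2), 20)
  resp2 <- matrix(runif(400), 20)
  out2 <- normalize_by_pooled_luminance(resp2, scene(lum, 0.5), 0.5, g_l = 0.05)
  expect_equal(out2, resp2 / (0.05 + lum), tolerance = 1e-9)
  # joint rescaling invariance in the g_l -> 0 limit
  outA <- normalize_by_pooled_luminance(resp2, scene(lum, 0.5), 3, g_l = 0)
  outB <- normalize_by_pooled_luminance(2 * resp2, scene(2 * lum, 0.5), 3, g_l = 0)
  expect_equal(outA, outB, tolerance = 1e-9)
  expect_error(normalize_by_pooled_luminance(resp2, scene(0 * lum, 0.5), 3, g_l = 0),
               "degenerate")
})

test_that("1-D Wasserstein distance has its metric and translation properties", {
  set.seed(21)
  expect_equal(wasserstein_1d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(wasserstein_1d(0, 2.5), 2.5)           # translated point masses
  u <- runif(400)
  expect_equal(wasserstein_1d(u, u + 0.3), 0.3, tolerance = 1e-9)
  for (i in 1:15) {
    x <- rnorm(sample(10:60, 1)); y <- rnorm(sample(10:60, 1), 1)
    z <- rexp(sample(10:60, 1))
    expect_equal(wasserstein_1d(x, y), wasserstein_1d(y, x), tolerance = 1e-12)
    expect_lte(wasserstein_1d(x, z),
               wasserstein_1d(x, y) + wasserstein_1d(y, z) + 1e-12)
    expect_equal(wasserstein_1d(x, y), grid_wasserstein(x, y), tolerance = 1e-3)
  }
  # equal-size fast path agrees with the CDF-integral path
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(wasserstein_1d(x, y), grid_wasserstein(x, y), tolerance = 1e-3)
})

test_that("pooling loss vanishes for identical, shape-preserved conditions", {
  x <- rnorm(300)
  pl <- pooling_loss(x, x, x)
  expect_equal(pl$loss, 0)
  # a purely scaling normalization preserves shape: term 2 stays 0
  raw <- exp(rnorm(300))
  pl2 <- pooling_loss(raw / 3, raw / 3, raw)
  expect_equal(pl2$term2, 0, tolerance = 1e-12)
})

test_that("a collapsing normalization costs the raw sample's mean deviation", {
  set.seed(31)
  raw <- rexp(500)
  collapsed <- rep(1, 500)
  pl <- pooling_loss(collapsed, collapsed, raw)
  mad_oracle <- mean(abs(raw - mean(raw)))
  expect_equal(pl$term2, mad_oracle, tolerance = 1e-9)
  expect_gte(pl$loss + 1e-12, max(pl$term1, pl$term2))  # Euclidean combination
  # figure-text reading uses the sunny condition for term 2
  pl_s <- pooling_loss(collapsed, collapsed, raw, sunny_raw = raw * 2,
                       term2_condition = "sunny")
  expect_equal(pl_s$term2, mean(abs(raw * 2 - mean(raw * 2))), tolerance = 1e-9)
})

test_that("pooling scan shows the structure/stability trade-off (U-shape)", {
  ens <- synthesize_scene_ensemble(seed = 1)
  scan <- scan_pooling_sizes(ens, seed = 1)
  s <- scan$summary
  n <- nrow(s)
  mid <- s$loss_mean[2:(n - 1)]
  expect_gt(s$loss_mean[1], min(mid))      # sub-degree pooling is worse
  expect_gt(s$loss_mean[n], min(mid))      # (half-)scene pooling is worse
  i_min <- which.min(s$loss_mean)
  expect_true(i_min > 1 && i_min < n)
  expect_gt(s$loss_std[1], s$loss_std[i_min])  # unstable at narrow pooling
  # bit-for-bit reproducibility of the full scan
  expect_identical(scan_pooling_sizes(ens, seed = 1)$summary, s)
})

test_that("a duplicated condition contributes zero condition mismatch", {
  cond <- default_scene_conditions()[c(1, 1), ]
  cond$label <- c("dup", "dup")
  ens <- synthesize_scene_ensemble(size = 64, conditions = cond, seed = 2)
  scan <- scan_pooling_sizes(ens, diameters = c(1, 4, 16), seed = 2)
  expect_true(all(scan$pairs$term1 == 0))
  expect_true(all(scan$pairs$loss == scan$pairs$term2))
})
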