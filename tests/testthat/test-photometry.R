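# closed-form squared Butterworth magnitude (forward-backward response),
# with the bilinear frequency mapping of the digital design
butter2_gain <- function(f, fc, rate, order) {
  ratio <- tan(pi * f / rate) / tan(pi * fc / rate)
  1 / (1 + ratio^(2 * order))
}

test_that("zero-phase Butterworth matches its closed-form response", {
  rate <- 40; fc <- 10
  t <- seq(0, 30, by = 1 / rate)
  mid <- 400:800                       # away from the edges
  # DC gain exactly 1
  expect_equal(lowpass_zero_phase(rep(3.3, 500), fc, rate), rep(3.3, 500),
               tolerance = 1e-9)
  # 1 Hz passband tone: amplitude within 1% of closed form, zero lag
  x <- sin(2 * pi * 1 * t)
  y <- lowpass_zero_phase(x, fc, rate)
  g <- max(abs(y[mid]))
  expect_equal(g, butter2_gain(1, fc, rate, 4), tolerance = 0.01)
  expect_equal(which.max(stats::ccf(y[mid], x[mid], lag.max = 5,
                                    plot = FALSE)$acf), 6L)  # lag 0
  # 5 Hz tone: still within 1% of the squared-magnitude response
  x5 <- sin(2 * pi * 5 * t)
  g5 <- max(abs(lowpass_zero_phase(x5, fc, rate)[mid]))
  expect_equal(g5, butter2_gain(5, fc, rate, 4), tolerance = 0.01)
  # 18 Hz stopband tone attenuated below 1% of input
  x18 <- sin(2 * pi * 18 * t)
  expect_lt(max(abs(lowpass_zero_phase(x18, fc, rate)[mid])), 0.01)
})

test_that("filter contracts: cutoff guard and monotone attenuation", {
  expect_error(lowpass_zero_phase(rnorm(100), 20, 40), "Nyquist")
  rate <- 40; t <- seq(0, 30, by = 1 / rate); mid <- 400:800
  gains <- vapply(c(2, 6, 10, 14, 18), function(f)
    max(abs(lowpass_zero_phase(sin(2 * pi * f * t), 10, rate)[mid])),
    numeric(1))
  expect_true(all(diff(gains) < 0))
})

test_that("RANSAC recovers exact and contaminated linear relations", {
  set.seed(31)
  ref <- 100 + cumsum(rnorm(1000, 0, 0.5))
  # noise-free: exact recovery
  fit <- fit_isosbestic(ref, 2 * ref + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$inlier_fraction, 1)
  # 10% gross outliers offset +50: slope within 1%, outliers excluded
  sig <- 2 * ref + 1 + rnorm(1000, 0, 0.2)
  out_idx <- sample(1000, 100)
  sig[out_idx] <- sig[out_idx] + 50
  fitc <- fit_isosbestic(ref, sig)
  expect_equal(fitc$slope, 2, tolerance = 0.01)
  expect_true(all(!fitc$inliers[out_idx]))
  # uncorrelated signal: slope near 0; the QC floor warns when raised
  # above the ~68% inlier share a 1-sigma MAD threshold retains on noise
  expect_warning(
    fit0 <- fit_isosbestic(ref, rnorm(1000),
                           preprocess_config(inlier_floor = 0.8)),
    "inlier fraction")
  expect_lt(abs(fit0$slope), 0.1)
  # guards
  expect_error(fit_isosbestic(rep(1, 200), rnorm(200)), "flat isosbestic")
  expect_error(fit_isosbestic(ref[1:50], sig[1:50]), "at least 100")
})

test_that("dF/F definition and guards", {
  expect_equal(compute_dff(2.0, 2.0), 0)
  expect_equal(compute_dff(2.2, 2.0), 0.1)
  expect_error(compute_dff(c(1, 2), c(1, 0)), "1 sample")
  # scale invariance: common positive gain leaves dff unchanged
  set.seed(5)
  sig <- 200 + rnorm(500); fitted <- 190 + rnorm(500, 0, 0.1)
  expect_equal(compute_dff(3 * sig, 3 * fitted), compute_dff(sig, fitted))
})

test_that("z-scoring: normalization, affine invariance, pooled hemispheres", {
  set.seed(6)
  x <- rnorm(1000, 5, 3)
  z <- zscore_within_animal(x)
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(stats::sd(z), 1, tolerance = 1e-9)
  expect_equal(zscore_within_animal(2 * x + 7), z)
  # pooled stats preserve the between-hemisphere offset in z units
  left <- rnorm(500); right <- rnorm(500) + 2
  zz <- zscore_within_animal(list(left = left, right = right))
  pooled_sd <- stats::sd(c(left, right))
  expect_equal(mean(zz$right) - mean(zz$left),
               (mean(right) - mean(left)) / pooled_sd)
  expect_error(zscore_within_animal(rep(1, 10)), "zero variance")
})

test_that("gaussian smoothing: identity, mass conservation, kernel peak", {
  x <- rnorm(50)
  expect_identical(gaussian_smooth(x, 0), x)
  expect_equal(gaussian_smooth(rep(2.5, 100), 4), rep(2.5, 100))
  # unit impulse: center weight equals the sigma = 4 kernel center, and
  # total mass 1 within 1e-9
  imp <- c(rep(0, 100), 1, rep(0, 100))
  sm <- gaussian_smooth(imp, 4)
  k <- gaussian_kernel(4)
  expect_equal(max(sm), k[(length(k) + 1) / 2])
  expect_equal(sum(sm), 1, tolerance = 1e-9)
  expect_error(gaussian_smooth(x, -1), "sigma")
})

test_that("preprocessing is deterministic and reports QC stats", {
  cfg <- sim_config(session_duration = 90, seed = 14)
  sim <- simulate_trajectory(cfg, maze_geometry())
  pm <- simulate_photometry(cfg, sim$truth)
  t1 <- preprocess_photometry(pm)
  t2 <- preprocess_photometry(pm)
  expect_identical(t1$zdff, t2$zdff)
  expect_equal(mean(t1$zdff), 0, tolerance = 1e-9)
  expect_equal(stats::sd(t1$zdff), 1, tolerance = 1e-9)
  fit <- attr(t1, "fit")
  expect_true(is.finite(fit$slope))
  expect_gt(fit$inlier_fraction, 0.5)
})

test_that("preprocess_animal pools hemispheres within animal", {
  cfg <- sim_config(session_duration = 90, seed = 15)
  sim <- simulate_trajectory(cfg, maze_geometry())
  left <- simulate_photometry(cfg, sim$truth, hemisphere = "left")
  cfg2 <- cfg; cfg2$seed <- cfg$seed + 1L
  right <- simulate_photometry(cfg2, sim$truth, hemisphere = "right")
  traces <- preprocess_animal(list(left, right))
  pooled <- c(traces[[1]]$zdff, traces[[2]]$zdff)
  expect_equal(mean(pooled), 0, tolerance = 1e-9)
  expect_equal(stats::sd(pooled), 1, tolerance = 1e-9)
})
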