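test_that("exact exponential decay is fitted perfectly", {
  tau <- c(0.2, 0.7, 1.2, 1.7, 2.2)
  fit <- fitPixelT1(exp(-tau / 1.0), tau)
  expect_true(fit$fitOk)
  expect_equal(fit$t1, 1.0, tolerance = 1e-8)
  expect_equal(fit$s0, 1.0, tolerance = 1e-8)

  # the alternative four-delay protocol works too
  tau4 <- c(0.5, 1.0, 1.5, 2.0)
  fit4 <- fitPixelT1(2.5 * exp(-tau4 / 0.8), tau4)
  expect_equal(fit4$t1, 0.8, tolerance = 1e-8)
  expect_equal(fit4$s0, 2.5, tolerance = 1e-8)

  # scale invariance: T1 unchanged, amplitude scales
  fitc <- fitPixelT1(7 * exp(-tau / 1.0), tau)
  expect_equal(fitc$t1, fit$t1, tolerance = 1e-8)
  expect_equal(fitc$s0, 7 * fit$s0, tolerance = 1e-7)

  # extra uniform decay adds rates: 1/T1' = 1/T1 + 1/tau_x
  fitx <- fitPixelT1(exp(-tau / 1.0) * exp(-tau / 2.0), tau)
  expect_equal(1 / fitx$t1, 1 / 1.0 + 1 / 2.0, tolerance = 1e-6)
})

test_that("degenerate pixel signals are flagged or rejected", {
  tau <- c(0.2, 0.7, 1.2, 1.7, 2.2)
  flat <- fitPixelT1(rep(3, 5), tau)            # no decay: T1 -> infinity
  expect_true(!flat$fitOk || flat$t1 > 6)
  expect_false(fitPixelT1(rep(0, 5), tau)$fitOk)
  expect_error(fitPixelT1(c(1, 0.5), c(0.2, 0.7)), "at least 3")
  expect_error(fitPixelT1(c(1, 0.5, 0.2), c(-0.2, 0.7, 1.2)), "positive")
})

test_that("nonlinear fit tracks the log-linear oracle under mild noise", {
  tau <- c(0.2, 0.7, 1.2, 1.7, 2.2)
  set.seed(1234)
  errNls <- errOracle <- numeric(200)
  for (i in seq_len(200)) {
    s <- exp(-tau / 1.0) * (1 + rnorm(5, 0, 0.01))
    errNls[i] <- fitPixelT1(s, tau)$t1 - 1.0
    errOracle[i] <- logLinearT1(s, tau) - 1.0
  }
  expect_lt(median(abs(errNls)), 0.05)
  # the two estimators weight the noise differently but must agree far
  # more closely with each other than with the truth
  expect_lt(median(abs(errNls - errOracle)), 0.02)
})

test_that("range filter keeps T1 = 6 s inclusively and rejects above", {
  tau <- c(0.2, 0.7, 1.2, 1.7, 2.2)
  t1true <- matrix(c(3.0, 6.0, 6.5, 1.0), 2, 2)
  m0 <- matrix(1, 2, 2)
  series <- analyticSeries(t1true, m0, tau, fov = c(2, 2))
  map <- buildT1Map(series, roi = matrix(TRUE, 2, 2))
  expect_true(map@mask[1, 1])   # 3.0 s
  expect_true(map@mask[2, 1])   # 6.0 s: inclusive upper bound
  expect_false(map@mask[1, 2])  # 6.5 s: outside physical range
  expect_true(map@mask[2, 2])
  expect_equal(map@t1[map@mask], c(3, 6, 1), tolerance = 1e-6)

  # out-of-ROI pixels are discarded even with valid T1
  roi <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  map2 <- buildT1Map(series, roi = roi)
  expect_false(map2@mask[2, 2])
  expect_true(all(!map2@mask | roi))
})

test_that("noise-free phantom round trip recovers the ground truth field", {
  # distortion-free settings: full-matrix acquisition, no apodization
  spec <- phantomSpec("control", gridShape = c(32L, 32L), fov = c(32, 32),
                      seed = 21)
  gt <- makePhantom(spec)
  acq <- acquisitionParams(nRead = 32L, nPhase = 32L,
                           noiseSigma = 0, timingJitter = 0)
  ks <- simulateDelaySeries(gt, acq)
  imgs <- reconstructSeries(ks, target = c(32L, 32L), apodize = FALSE)
  map <- buildT1Map(imgs, roi = gt@roiMask)
  expect_true(all(map@mask == gt@roiMask))
  rel <- abs(map@t1[map@mask] - gt@t1Field[gt@roiMask]) /
    gt@t1Field[gt@roiMask]
  expect_lt(max(rel), 1e-6)
})

test_that("frame scaling leaves the T1 map unchanged", {
  tau <- c(0.2, 0.7, 1.2, 1.7, 2.2)
  set.seed(31)
  t1true <- matrix(runif(16, 0.7, 2), 4, 4)
  series <- analyticSeries(t1true, matrix(1, 4, 4), tau, fov = c(4, 4))
  scaled <- new("ImageSeries", frames = lapply(frames(series), `*`, 5),
                delays = tau, fov = c(4, 4), pixelSize = c(1, 1))
  m1 <- buildT1Map(series, roi = matrix(TRUE, 4, 4))
  m2 <- buildT1Map(scaled, roi = matrix(TRUE, 4, 4))
  expect_equal(m2@t1, m1@t1, tolerance = 1e-7)
  expect_equal(m2@s0, 5 * m1@s0, tolerance = 1e-6)
})

test_that("ROI detection matches the ventilated phantom region", {
  gt <- makePhantom(phantomSpec("control", seed = 41))
  ks <- simulateDelaySeries(gt, acquisitionParams(noiseSigma = 0,
                                                  timingJitter = 0))
  imgs <- reconstructSeries(ks, truncateTo = c(32L, NA))
  roi <- roiFromFirstImage(frames(imgs)[[1]])
  dice <- 2 * sum(roi & gt@roiMask) / (sum(roi) + sum(gt@roiMask))
  expect_gte(dice, 0.95)

  expect_error(roiFromFirstImage(matrix(0, 8, 8)), "empty ROI")
  img <- matrix(0, 8, 8); img[3:5, 3:5] <- 2
  expect_identical(roiFromFirstImage(img, thresholdFrac = 0,
                                     minRegion = 1L), img > 0)
})
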