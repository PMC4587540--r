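test_that("sine-bell squared window matches its closed form and is symmetric", {
  w4 <- sineBellSquared(4)
  expect_equal(w4, c(sin(pi / 8)^2, sin(3 * pi / 8)^2,
                     sin(3 * pi / 8)^2, sin(pi / 8)^2))
  expect_equal(w4, c(0.146447, 0.853553, 0.853553, 0.146447),
               tolerance = 1e-6)
  expect_equal(sineBellSquared(2), c(0.5, 0.5))
  for (n in c(3L, 8L, 32L, 33L))
    expect_equal(sineBellSquared(n), rev(sineBellSquared(n)))
  # no zeroed sample at the acquired edges
  expect_true(all(sineBellSquared(32) > 0))

  ones <- matrix(1 + 0i, 2, 2)
  expect_equal(apodizeSineBellSquared(ones),
               matrix(0.25 + 0i, 2, 2))
})

test_that("zero filling is centred and conserves sample energy", {
  set.seed(7)
  k <- matrix(complex(real = rnorm(32 * 32), imaginary = rnorm(32 * 32)),
              32, 32)
  z <- zeroFill(k, c(64L, 64L))
  expect_identical(dim(z), c(64L, 64L))
  expect_equal(sum(Mod(z)^2), sum(Mod(k)^2))
  expect_identical(zeroFill(k, c(32L, 32L)), k)
  expect_error(zeroFill(k, c(16L, 64L)), "target")

  # a delta at the k-space centre stays at the centre after padding
  delta <- matrix(0 + 0i, 32, 32); delta[17, 17] <- 1
  zd <- zeroFill(delta, c(64L, 64L))
  expect_equal(which(Mod(zd) > 0), which(matrix(seq_len(64 * 64), 64) ==
                                           ((33 - 1) * 64 + 33)))
})

test_that("reconstruction geometry yields the stated pixel size", {
  k <- matrix(0 + 0i, 32, 32); k[17, 17] <- 1
  rec <- reconstructFrame(k, fov = c(50.9, 40.7))
  expect_identical(dim(rec$image), c(64L, 64L))
  expect_equal(rec$pixelSize, c(50.9, 40.7) / 64)
  expect_true(all(abs(rec$pixelSize - c(0.795, 0.635)) < 1e-3))

  # a centred delta transforms to a flat-magnitude image scaled by the
  # window's centre gain
  expect_lt(diff(range(rec$image)), 1e-12 * max(rec$image))
  expect_gt(min(rec$image), 0)

  # zero k-space gives a zero image
  expect_true(all(reconstructFrame(matrix(0 + 0i, 32, 32),
                                   fov = c(50.9, 40.7))$image == 0))
})

test_that("unitary transform satisfies Parseval and positive homogeneity", {
  set.seed(8)
  k <- matrix(complex(real = rnorm(1024), imaginary = rnorm(1024)), 32, 32)
  rec <- reconstructFrame(k, fov = c(50.9, 40.7), apodize = FALSE)
  expect_equal(sum(rec$image^2), sum(Mod(k)^2), tolerance = 1e-10)

  rec3 <- reconstructFrame(3 * k, fov = c(50.9, 40.7))
  rec1 <- reconstructFrame(k, fov = c(50.9, 40.7))
  expect_equal(rec3$image, 3 * rec1$image, tolerance = 1e-12)
})

test_that("image centre corresponds to k-space centre", {
  # an off-centre Gaussian blob must reconstruct at its true location
  n <- 32L
  r <- row(matrix(0, n, n)); c_ <- col(matrix(0, n, n))
  blob <- exp(-((r - 11)^2 + (c_ - 23)^2) / 4)
  k <- squareT1:::kspaceFromImage(blob)
  rec <- reconstructFrame(k, fov = c(n, n), target = c(n, n),
                          apodize = FALSE)
  peak <- which(rec$image == max(rec$image), arr.ind = TRUE)
  expect_equal(as.integer(peak), c(11L, 23L))
  expect_equal(rec$image, blob, tolerance = 1e-10)
})

test_that("series reconstruction truncates the read dimension on request", {
  gt <- flatPhantom(n = 64L, t1 = 1.0)
  ks <- simulateDelaySeries(gt, acquisitionParams(noiseSigma = 0,
                                                  timingJitter = 0))
  imgs <- reconstructSeries(ks, truncateTo = c(32L, NA))
  expect_s4_class(imgs, "ImageSeries")
  expect_identical(dim(frames(imgs)[[1]]), c(64L, 64L))
  expect_equal(imgs@pixelSize, c(50.9, 40.7) / 64)
  expect_error(reconstructSeries(ks, truncateTo = c(128L, NA)),
               "truncateTo")
})
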