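test_that("apparent polarization multiplies polarization by krypton fraction", {
  expect_equal(apparentPolarization(0.165, 0.15), 0.02475)
  expect_equal(signif(100 * apparentPolarization(0.165, 0.15), 2), 2.5)
  expect_equal(apparentPolarization(0.42, 1), 0.42)
  expect_equal(apparentPolarization(0, 0.15), 0)
  expect_error(apparentPolarization(1.2, 0.15), "polarization")
  expect_error(apparentPolarization(0.2, 0), "krypton")
  expect_error(apparentPolarization(-0.1, 0.5), "polarization")
})

test_that("VFA schedule has the closed form and constant per-line signal", {
  expect_equal(vfaSchedule(1), pi / 2)
  th32 <- vfaSchedule(32)
  expect_equal(th32[32], pi / 2)
  expect_equal(th32[1], atan(1 / sqrt(31)))
  expect_equal(th32[1] * 180 / pi, 10.1821, tolerance = 1e-4)
  # each excitation consumes the remaining magnetization so that the
  # transverse signal is 1/sqrt(n) for every line
  for (n in c(2L, 5L, 16L, 32L, 64L)) {
    th <- vfaSchedule(n)
    signal <- sin(th) * c(1, cumprod(cos(th))[-n])
    expect_equal(signal, rep(1 / sqrt(n), n), tolerance = 1e-12)
  }
  expect_error(vfaSchedule(0), "integer >= 1")
})

test_that("T1 from surface-to-volume ratio obeys the proportionality law", {
  set.seed(42)
  sv <- matrix(runif(64, 0.5, 3), 8, 8)
  expect_equal(t1FromSV(sv, 2), 2 / sv)
  expect_equal(t1FromSV(2 * sv, 1.3), t1FromSV(sv, 1.3) / 2)
  expect_equal(t1FromSV(sv, 2.6), 2 * t1FromSV(sv, 1.3))
  expect_equal(t1FromSV(1.7, 1.7), 1)
  expect_error(t1FromSV(-1, 2), "positive")
  expect_error(t1FromSV(sv, -2), "kappa")

  # doubling MAA 2.26-fold lengthens T1 by sqrt(2.26) under the default
  # square-root coupling: 1.0 s -> ~1.50 s
  svRef <- 1.8; t1Ref <- 1.0; kappa <- t1Ref * svRef
  t1 <- t1FromSV(svFromMAA(2.26 * 2.7, svRef, 2.7), kappa)
  expect_equal(t1, sqrt(2.26), tolerance = 1e-12)
  expect_equal(t1, 1.5033, tolerance = 1e-4)
})

test_that("phantom presets produce the expected bimodal ground truth", {
  spec <- phantomSpec("control", seed = 5)
  gt <- makePhantom(spec)
  par <- gt@t1Field[gt@labels == 1L]
  air <- gt@t1Field[gt@labels == 2L]
  expect_gt(length(par), 500)
  expect_gt(length(air), 50)
  expect_equal(mean(par), 1.0062, tolerance = 0.05)
  expect_equal(mean(air), 1.2699, tolerance = 0.2)
  expect_lt(mean(par), mean(air))

  el <- makePhantom(phantomSpec("elastase", seed = 5))
  expect_equal(mean(el@t1Field[el@labels == 1L]), 1.25358, tolerance = 0.06)
  expect_equal(mean(el@t1Field[el@labels == 2L]), 1.7009, tolerance = 0.25)

  # determinism: identical spec (incl. seed) gives bit-identical fields
  gt2 <- makePhantom(phantomSpec("control", seed = 5))
  expect_identical(gt@t1Field, gt2@t1Field)
  expect_identical(gt@m0Field, gt2@m0Field)

  # full ventilation defect silences the phantom
  dead <- makePhantom(phantomSpec("control", defectFraction = 1, seed = 5))
  expect_true(all(dead@m0Field == 0))
  expect_false(any(dead@roiMask))

  # MAA coupling rescales the alveolar (fast) mode
  big <- makePhantom(phantomSpec("control", maa = 2.26 * 2.7, maaRef = 2.7,
                                 seed = 5))
  expect_equal(mean(big@t1Field[big@labels == 1L]) / mean(par), sqrt(2.26),
               tolerance = 0.01)
})

test_that("simulated delay series decays exponentially with delay", {
  gt <- flatPhantom(n = 64L, t1 = 1.0)
  acq <- acquisitionParams(noiseSigma = 0, timingJitter = 0)
  ks <- simulateDelaySeries(gt, acq, seed = 1)
  expect_equal(delays(ks), c(0.2, 0.7, 1.2, 1.7, 2.2))
  expect_identical(dim(frames(ks)[[1]]), c(64L, 32L))

  # uniform T1: every frame is a global rescaling, so the reconstructed
  # intensity ratio is exp(-2.0) at every pixel that carries signal
  imgs <- reconstructSeries(ks, truncateTo = c(32L, NA))
  r1 <- frames(imgs)[[1]]; r5 <- frames(imgs)[[5]]
  keep <- r1 > 1e-3 * max(r1)
  expect_equal(r5[keep] / r1[keep],
               rep(exp(-2), sum(keep)), tolerance = 1e-10)

  # defect phantom with no noise yields all-zero frames
  dead <- makePhantom(phantomSpec("control", defectFraction = 1, seed = 3))
  ksDead <- simulateDelaySeries(dead, acq, seed = 1)
  expect_true(all(vapply(frames(ksDead),
                         function(f) all(Mod(f) == 0), logical(1))))
})

test_that("simulation is deterministic under a fixed seed", {
  gt <- makePhantom(phantomSpec("control", seed = 9))
  acq <- acquisitionParams()  # noise and jitter on
  a <- simulateDelaySeries(gt, acq, seed = 77)
  b <- simulateDelaySeries(gt, acq, seed = 77)
  d <- simulateDelaySeries(gt, acq, seed = 78)
  expect_identical(frames(a), frames(b))
  expect_identical(a@actualDelays, b@actualDelays)
  expect_false(identical(frames(a), frames(d)))
  # analysis always sees the nominal delays
  expect_identical(delays(a), acq@delays)
})

test_that("intra-scan decay shortens the apparent relaxation additively", {
  gt <- flatPhantom(n = 32L, t1 = 1.0, fov = c(32, 32))
  acqOff <- acquisitionParams(nRead = 32L, nPhase = 32L,
                              noiseSigma = 0, timingJitter = 0)
  acqOn <- acquisitionParams(nRead = 32L, nPhase = 32L, noiseSigma = 0,
                             timingJitter = 0, intraScanDecay = TRUE)
  ksOff <- simulateDelaySeries(gt, acqOff)
  ksOn <- simulateDelaySeries(gt, acqOn)
  # the DC line is acquired mid-train; total decay over 32 lines of TR is
  # bounded by exp(-31 * 0.0126) ~ 0.68, so frames differ but modestly
  e0 <- sum(Mod(frames(ksOff)[[1]])^2)
  e1 <- sum(Mod(frames(ksOn)[[1]])^2)
  expect_lt(e1, e0)
  expect_gt(e1, 0.4 * e0)
})
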