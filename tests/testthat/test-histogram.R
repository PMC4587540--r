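test_that("binning follows the fixed scheme with lower-bin edge assignment", {
  h <- binT1(1.00)
  expect_s4_class(h, "T1Histogram")
  expect_length(h@counts, 200L)
  expect_equal(diff(h@breaks), rep(0.03, 200), tolerance = 1e-12)
  expect_equal(range(h@breaks), c(0, 6))     # span equals the T1 ceiling
  # 1.00 s falls in the bin covering (0.99, 1.02]
  i <- which(h@counts == 1)
  expect_equal(c(h@breaks[i], h@breaks[i + 1]), c(0.99, 1.02))

  # an exact edge value belongs to the lower bin, like the inclusive 6 s
  expect_equal(which(binT1(0.99)@counts == 1), 33L)
  expect_equal(which(binT1(6.0)@counts == 1), 200L)
  expect_equal(which(binT1(0.0300000001)@counts == 1), 2L)

  set.seed(2)
  vals <- runif(500, 0.1, 5.9)
  expect_equal(sum(binT1(vals)@counts), 500)
  expect_error(binT1(numeric(0)), "no masked")
  expect_error(binT1(c(1, 6.5)), "lie in")
})

test_that("bimodal fit recovers known mixture parameters exactly when noise free", {
  # parameters of a real control lung: modes (0.9958, 0.19619) and
  # (1.2353, 0.53927)
  h <- mixtureHistogram(amp = c(900, 260),
                        mu = c(0.9958, 1.2353),
                        fwhm = c(0.19619, 0.53927))
  fit <- fitBimodal(h)
  expect_false(fit@degenerate)
  ev <- evT1(fit); fw <- fwhmT1(fit); am <- amplitudes(fit)
  expect_equal(unname(ev), c(0.9958, 1.2353), tolerance = 1e-6)
  expect_equal(unname(fw), c(0.19619, 0.53927), tolerance = 1e-6)
  expect_equal(unname(am), c(900, 260), tolerance = 1e-5)
  expect_lt(fit@residual, 1e-6)

  # FWHM identity: the fitted sigma of a pure Gaussian comes back as
  # 2 sqrt(2 ln 2) sigma
  sigma <- 0.12
  h1 <- mixtureHistogram(500, 1.1, 2 * sqrt(2 * log(2)) * sigma)
  f1 <- fitBimodal(h1)
  expect_true(f1@degenerate)
  expect_equal(unname(fwhmT1(f1)) / (2 * sqrt(2 * log(2))), sigma,
               tolerance = 1e-6)
})

test_that("bimodal fit recovers mixture parameters from sampled data", {
  set.seed(99)
  n <- 20000
  comp <- rbinom(n, 1, 0.4)
  vals <- ifelse(comp == 0, rnorm(n, 1.0, 0.0637), rnorm(n, 1.3, 0.17))
  vals <- vals[vals > 0 & vals <= 6]
  fit <- fitBimodal(binT1(vals))
  expect_false(fit@degenerate)
  ev <- evT1(fit); fw <- fwhmT1(fit)
  expect_equal(unname(ev[["fast"]]), 1.0, tolerance = 0.02)
  expect_equal(unname(ev[["slow"]]), 1.3, tolerance = 0.02)
  toFwhm <- 2 * sqrt(2 * log(2))
  expect_lt(abs(fw[["fast"]] - toFwhm * 0.0637) / (toFwhm * 0.0637), 0.15)
  expect_lt(abs(fw[["slow"]] - toFwhm * 0.17) / (toFwhm * 0.17), 0.15)
})

test_that("single-mode histograms are flagged degenerate, not forced bimodal", {
  h <- mixtureHistogram(400, 1.05, 0.25)
  fit <- fitBimodal(h)
  expect_true(fit@degenerate)
  expect_equal(nrow(fit@modes), 1L)
  expect_equal(unname(evT1(fit)), 1.05, tolerance = 1e-4)
})

test_that("refitting from the converged optimum does not move it", {
  h <- mixtureHistogram(amp = c(900, 260), mu = c(0.9958, 1.2353),
                        fwhm = c(0.19619, 0.53927))
  x <- binCentres(h)
  first <- squareT1:::.fitGaussians(x, h@counts, mu = c(1.0, 1.3),
                                    sigma = c(0.1, 0.2), amp = c(800, 300))
  again <- squareT1:::.fitGaussians(x, h@counts, mu = first$mu,
                                    sigma = first$sigma, amp = first$amp)
  expect_equal(again$mu, first$mu, tolerance = 1e-8)
  expect_equal(again$sigma, first$sigma, tolerance = 1e-8)
  expect_equal(again$amp, first$amp, tolerance = 1e-8)
})

test_that("mode labels are ordered fast < slow regardless of input order", {
  set.seed(5)
  vals <- c(rnorm(3000, 1.0, 0.07), rnorm(1500, 1.45, 0.2))
  vals <- vals[vals > 0 & vals <= 6]
  f1 <- fitBimodal(binT1(vals))
  f2 <- fitBimodal(binT1(rev(vals)))
  expect_identical(f1@modes$mode, c("fast", "slow"))
  expect_equal(f1@modes$ev, f2@modes$ev, tolerance = 1e-9)
  expect_lt(evT1(f1)[["fast"]], evT1(f1)[["slow"]])
})

test_that("pooling histograms sums counts and checks binning", {
  set.seed(6)
  h1 <- binT1(runif(300, 0.5, 2))
  h2 <- binT1(runif(200, 1, 3))
  pooled <- poolHistograms(list(h1, h2))
  expect_equal(pooled@counts, h1@counts + h2@counts)
  expect_equal(sum(pooled@counts), 500)
  self <- poolHistograms(list(h1, h1))
  expect_equal(self@counts, 2 * h1@counts)

  coarse <- binT1(runif(100, 0.5, 2), binWidth = 0.06, nBins = 100L)
  expect_error(poolHistograms(list(h1, coarse)), "mismatched")

  # pooled fit lands between the per-histogram mode centres
  set.seed(7)
  a <- c(rnorm(4000, 0.98, 0.08), rnorm(1500, 1.30, 0.18))
  b <- c(rnorm(4000, 1.03, 0.08), rnorm(1500, 1.36, 0.18))
  ha <- binT1(a[a > 0 & a <= 6]); hb <- binT1(b[b > 0 & b <= 6])
  fa <- evT1(fitBimodal(ha)); fb <- evT1(fitBimodal(hb))
  fp <- evT1(fitBimodal(poolHistograms(list(ha, hb))))
  expect_gte(fp[["fast"]], min(fa[["fast"]], fb[["fast"]]) - 0.01)
  expect_lte(fp[["fast"]], max(fa[["fast"]], fb[["fast"]]) + 0.01)
})
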