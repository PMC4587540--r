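# Independent oracles and small builders used across the test files.

# Exact two-sided permutation test on the difference of group means:
# enumerates every assignment of the pooled values to a group of size
# length(x), and returns the fraction of assignments whose absolute mean
# difference is at least the observed one.
permutationP <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  obs <- abs(mean(x) - mean(y))
  combos <- utils::combn(length(pooled), nx)
  diffs <- apply(combos, 2, function(idx)
    abs(mean(pooled[idx]) - mean(pooled[-idx])))
  mean(diffs >= obs - 1e-12)
}

# Log-linear (brute-force) estimate of T1 from a positive decay series.
logLinearT1 <- function(signal, delayTimes) {
  cf <- stats::coef(stats::lm(log(signal) ~ delayTimes))
  -1 / cf[[2]]
}

# Analytic magnitude delay series for a given T1/m0 field (no acquisition
# or reconstruction chain involved).
analyticSeries <- function(t1, m0, delayTimes, fov = c(50.9, 40.7)) {
  frames <- lapply(delayTimes, function(tau) {
    s <- m0
    live <- m0 > 0
    s[live] <- m0[live] * exp(-tau / t1[live])
    s
  })
  new("ImageSeries", frames = frames, delays = delayTimes,
      fov = fov, pixelSize = fov / dim(m0))
}

# Uniform-T1 disc phantom: the simplest ground truth with a flat T1 field.
flatPhantom <- function(n = 64L, t1 = 1.0, fov = c(50.9, 40.7)) {
  r <- row(matrix(0, n, n)); c_ <- col(matrix(0, n, n))
  disc <- (r - n / 2)^2 + (c_ - n / 2)^2 <= (0.35 * n)^2
  t1f <- matrix(0, n, n); t1f[disc] <- t1
  m0 <- matrix(0, n, n); m0[disc] <- 1
  new("GroundTruth", t1Field = t1f, m0Field = m0, roiMask = disc,
      labels = matrix(0L, n, n), fov = fov)
}

# Noise-free Gaussian-mixture histogram evaluated at bin centres.
mixtureHistogram <- function(amp, mu, fwhm, binWidth = 0.03, nBins = 200L) {
  breaks <- seq(0, nBins * binWidth, by = binWidth)
  x <- (head(breaks, -1) + tail(breaks, -1)) / 2
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  counts <- 0
  for (i in seq_along(amp))
    counts <- counts + amp[i] * exp(-(x - mu[i])^2 / (2 * sigma[i]^2))
  new("T1Histogram", breaks = breaks, counts = counts)
}
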