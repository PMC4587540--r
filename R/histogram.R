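#' Bin masked T1 values into the fixed histogram scheme
#'
#' Bins the valid (masked) T1 values of a map into `nBins` intervals of
#' width `binWidth` starting at zero — by default 200 intervals of 0.03 s,
#' spanning exactly the 0--6 s physical acceptance window of the range
#' filter. A value falling exactly on a bin edge is assigned to the lower
#' bin, so the ceiling value T1 = 6 s (which the range filter keeps) lands
#' in the last bin.
#'
#' @param t1map A [T1Map-class] with at least one masked pixel, or a
#'   numeric vector of T1 values in `(0, nBins * binWidth]`.
#' @param binWidth Bin width in s, default 0.03.
#' @param nBins Number of bins, default 200.
#' @return A [T1Histogram-class]; `sum(counts)` equals the number of masked
#'   pixels.
#' @export
binT1 <- function(t1map, binWidth = 0.03, nBins = 200L) {
  vals <- if (is(t1map, "T1Map")) t1Values(t1map) else as.numeric(t1map)
  if (length(vals) == 0L) stop("no masked T1 values to bin")
  span <- nBins * binWidth
  if (any(vals <= 0) || any(vals > span + 1e-9))
    stop(sprintf("T1 values must lie in (0, %g] s", span))
  # edge values belong to the lower bin: ceiling with a tolerance for the
  # floating-point representation of edge multiples
  idx <- pmax(1L, as.integer(ceiling(vals / binWidth - 1e-9)))
  idx <- pmin(idx, nBins)
  new("T1Histogram",
      breaks = seq(0, span, by = binWidth),
      counts = as.numeric(tabulate(idx, nbins = nBins)))
}

#' Bin centres of a T1 histogram
#' @param hist A [T1Histogram-class].
#' @return Numeric vector of bin mid-points (s).
#' @export
binCentres <- function(hist) {
  stopifnot(is(hist, "T1Histogram"))
  (utils::head(hist@breaks, -1) + utils::tail(hist@breaks, -1)) / 2
}

#' Pool T1 histograms across lungs
#'
#' Elementwise sum of counts over histograms with identical binning, used to
#' build the combined group histograms.
#'
#' @param hists List of [T1Histogram-class] objects with identical breaks.
#' @return A [T1Histogram-class] with the summed counts.
#' @export
poolHistograms <- function(hists) {
  if (length(hists) == 0L) stop("no histograms to pool")
  stopifnot(all(vapply(hists, is, logical(1), "T1Histogram")))
  br <- hists[[1]]@breaks
  same <- vapply(hists, function(h)
    length(h@breaks) == length(br) && all(abs(h@breaks - br) < 1e-9),
    logical(1))
  if (!all(same)) stop("histograms have mismatched binning")
  new("T1Histogram", breaks = br,
      counts = Reduce(`+`, lapply(hists, slot, "counts")))
}

# locate local maxima of a (smoothed) count vector; returns indices sorted
# by decreasing height, discarding maxima below heightFrac of the tallest
.findPeaks <- function(y, heightFrac = 0.05) {
  n <- length(y)
  i <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  i <- i[y[i] > heightFrac * max(y)]
  i[order(y[i], decreasing = TRUE)]
}

# shoulder candidates: local minima of the second difference (regions of
# strong negative curvature that are not free-standing maxima), the way
# automated multipeak detection finds partially merged components
.findShoulders <- function(y, heightFrac = 0.05) {
  n <- length(y)
  d2 <- c(0, diff(diff(y)), 0)
  i <- which(d2[2:(n - 1)] < d2[1:(n - 2)] & d2[2:(n - 1)] <= d2[3:n]) + 1L
  i <- i[d2[i] < 0.02 * min(d2) & y[i] > heightFrac * max(y)]
  i[order(d2[i])]
}

# half-height width (in x units) of the peak at index i0, from the smoothed
# curve; falls back to 2 bins when the flanks never drop below half height
.halfWidth <- function(x, y, i0) {
  half <- y[i0] / 2
  left <- i0; while (left > 1L && y[left] > half) left <- left - 1L
  right <- i0; while (right < length(y) && y[right] > half) right <- right + 1L
  w <- x[right] - x[left]
  max(w, 2 * (x[2] - x[1]))
}

#' Decompose a T1 histogram into two Gaussian modes
#'
#' Models the bin-centre counts as the sum of two Gaussians
#' \eqn{\sum_m A_m \exp(-(T_1-\mu_m)^2/(2\sigma_m^2))}, reflecting the
#' distinct alveolar (fast-relaxing, high surface-to-volume) and conducting
#' airway (slow-relaxing) compartments of the lung. Automated peak picking
#' initialises the fit: counts are smoothed with a short moving average, the
#' two highest local maxima give the initial centres and amplitudes, and
#' the local half-height widths the initial sigmas. Unweighted nonlinear
#' least squares refines all six parameters. Each mode is reported through
#' its expected value EV (the centre \eqn{\mu}) and full width at half
#' maximum \eqn{FWHM = 2\sqrt{2\ln 2}\,\sigma}; the mode with the smaller
#' centre is labelled `fast`. A histogram without two discernible maxima is
#' fitted with a single Gaussian and flagged degenerate rather than being
#' silently forced bimodal.
#'
#' @param hist A [T1Histogram-class].
#' @param smoothBins Width (odd number of bins) of the moving-average kernel
#'   used only for peak picking, default 5.
#' @param minSeparation Minimum separation of the two initial centres in
#'   bins, default 3.
#' @return A [BimodalFit-class].
#' @examples
#' vals <- c(rnorm(1200, 1.0, 0.08), rnorm(500, 1.3, 0.2))
#' fit <- fitBimodal(binT1(vals[vals > 0 & vals <= 6]))
#' evT1(fit)
#' @export
fitBimodal <- function(hist, smoothBins = 5L, minSeparation = 3L) {
  stopifnot(is(hist, "T1Histogram"))
  validObject(hist)
  x <- binCentres(hist)
  y <- hist@counts
  if (sum(y) == 0) stop("histogram is empty")

  kern <- rep(1 / smoothBins, smoothBins)
  ys <- as.numeric(stats::filter(y, kern, sides = 2))
  ys[is.na(ys)] <- y[is.na(ys)]
  peaks <- .findPeaks(ys)

  # the two highest sufficiently separated maxima; if only one mode stands
  # free, look for a merged second mode as a curvature shoulder
  pk <- if (length(peaks)) peaks[1] else which.max(ys)
  for (p in peaks[-1]) {
    if (abs(p - pk[1]) >= minSeparation) { pk <- c(pk, p); break }
  }
  if (length(pk) < 2L) {
    for (s in .findShoulders(ys)) {
      if (abs(s - pk[1]) >= minSeparation) { pk <- c(pk, s); break }
    }
  }
  toFwhm <- 2 * sqrt(2 * log(2))

  if (length(pk) < 2L) {
    fit1 <- .fitGaussians(x, y, mu = x[pk], sigma = .halfWidth(x, ys, pk) / toFwhm,
                          amp = max(y[pk], ys[pk]))
    modes <- data.frame(mode = "fast", ev = fit1$mu, fwhm = toFwhm * fit1$sigma,
                        amplitude = fit1$amp, stringsAsFactors = FALSE)
    return(new("BimodalFit", modes = modes, degenerate = TRUE,
               residual = fit1$rms, fitted = fit1$fitted, histogram = hist))
  }

  mu0 <- x[pk]
  sig0 <- vapply(pk, function(i) .halfWidth(x, ys, i) / toFwhm, numeric(1))
  # a half-height walk from a merged shoulder can run across the main peak;
  # cap the initial width at the peak separation
  sig0 <- pmin(sig0, abs(diff(mu0)))
  amp0 <- pmax(y[pk], ys[pk])
  fit2 <- .fitGaussians(x, y, mu = mu0, sigma = sig0, amp = amp0)

  # guard against pathological optima of a weakly bimodal histogram: a
  # pseudo-baseline component (huge width), collapsed centres, or a
  # vanishing component all mean there is only one credible mode
  binW <- x[2] - x[1]
  sane <- all(toFwhm * fit2$sigma < 2) &&
    abs(diff(fit2$mu)) >= minSeparation * binW &&
    min(fit2$amp) > 0.02 * max(fit2$amp)
  if (!sane) {
    i0 <- which.max(ys)
    fit1 <- .fitGaussians(x, y, mu = x[i0],
                          sigma = .halfWidth(x, ys, i0) / toFwhm,
                          amp = max(y[i0], ys[i0]))
    modes <- data.frame(mode = "fast", ev = fit1$mu,
                        fwhm = toFwhm * fit1$sigma,
                        amplitude = fit1$amp, stringsAsFactors = FALSE)
    return(new("BimodalFit", modes = modes, degenerate = TRUE,
               residual = fit1$rms, fitted = fit1$fitted, histogram = hist))
  }

  ord <- order(fit2$mu)
  modes <- data.frame(mode = c("fast", "slow"),
                      ev = fit2$mu[ord],
                      fwhm = toFwhm * fit2$sigma[ord],
                      amplitude = fit2$amp[ord],
                      stringsAsFactors = FALSE)
  new("BimodalFit", modes = modes, degenerate = FALSE,
      residual = fit2$rms, fitted = fit2$fitted, histogram = hist)
}

# unweighted least-squares fit of 1 or 2 Gaussians to (x, y)
.fitGaussians <- function(x, y, mu, sigma, amp) {
  m <- length(mu)
  sigma <- pmax(sigma, (x[2] - x[1]) / 4)
  amp <- pmax(amp, 1e-6)
  model <- function(par) {
    out <- 0
    for (i in seq_len(m))
      out <- out + par[3 * i - 2] *
        exp(-(x - par[3 * i - 1])^2 / (2 * par[3 * i]^2))
    out
  }
  par0 <- as.numeric(rbind(amp, mu, sigma))
  lower <- rep(c(1e-9, min(x), (x[2] - x[1]) / 10), m)
  upper <- rep(c(Inf, max(x), max(x) - min(x)), m)
  res <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper,
    fn = function(par) y - model(par),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  par <- res$par
  fitted <- model(par)
  idx <- seq_len(m)
  list(amp = par[3 * idx - 2], mu = par[3 * idx - 1],
       sigma = abs(par[3 * idx]),
       rms = sqrt(mean((y - fitted)^2)), fitted = fitted)
}
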