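#' Accessors for delay-series and map objects
#'
#' `delays()` returns the nominal post-inhalation delays, `frames()` the list
#' of per-delay matrices, `fovOf()` the field of view in mm. `t1Values()`
#' extracts the vector of valid (masked) T1 values from a [T1Map-class];
#' `validMask()` its validity mask. `evT1()`, `fwhmT1()` and `amplitudes()`
#' return the named per-mode biomarkers of a [BimodalFit-class].
#'
#' @param object An object of the appropriate class.
#' @return See the individual descriptions.
#' @name accessors
#' @aliases delays frames fovOf t1Values validMask evT1 fwhmT1 amplitudes
NULL

#' @rdname accessors
#' @export
setGeneric("delays", function(object) standardGeneric("delays"))

#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))

#' @rdname accessors
#' @export
setGeneric("fovOf", function(object) standardGeneric("fovOf"))

#' @rdname accessors
#' @export
setGeneric("t1Values", function(object) standardGeneric("t1Values"))

#' @rdname accessors
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))

#' @rdname accessors
#' @export
setGeneric("evT1", function(object) standardGeneric("evT1"))

#' @rdname accessors
#' @export
setGeneric("fwhmT1", function(object) standardGeneric("fwhmT1"))

#' @rdname accessors
#' @export
setGeneric("amplitudes", function(object) standardGeneric("amplitudes"))

#' Reconstruct magnitude images from k-space
#'
#' @param object A [KSpaceSeries-class] (or a single complex matrix for
#'   [reconstructFrame()]).
#' @param ... Options passed on to the frame-level reconstruction.
#' @return An [ImageSeries-class].
#' @seealso [reconstructFrame()]
#' @export
setGeneric("reconstructSeries", function(object, ...)
  standardGeneric("reconstructSeries"))

setMethod("delays", "KSpaceSeries", function(object) object@delays)
setMethod("delays", "ImageSeries", function(object) object@delays)
setMethod("frames", "KSpaceSeries", function(object) object@frames)
setMethod("frames", "ImageSeries", function(object) object@frames)
setMethod("fovOf", "KSpaceSeries", function(object) object@fov)
setMethod("fovOf", "ImageSeries", function(object) object@fov)
setMethod("fovOf", "T1Map", function(object) object@fov)
setMethod("fovOf", "GroundTruth", function(object) object@fov)

setMethod("t1Values", "T1Map", function(object) object@t1[object@mask])
setMethod("validMask", "T1Map", function(object) object@mask)

setMethod("evT1", "BimodalFit", function(object)
  stats::setNames(object@modes$ev, object@modes$mode))
setMethod("fwhmT1", "BimodalFit", function(object)
  stats::setNames(object@modes$fwhm, object@modes$mode))
setMethod("amplitudes", "BimodalFit", function(object)
  stats::setNames(object@modes$amplitude, object@modes$mode))

setMethod("show", "AcquisitionParams", function(object) {
  cat("AcquisitionParams:",
      sprintf("TE %.1f ms, TR %.1f ms, matrix %d x %d",
              1e3 * object@te, 1e3 * object@tr, object@nRead, object@nPhase),
      "\n  delays (s):", paste(format(object@delays), collapse = ", "),
      sprintf("\n  noise sigma %.3g, timing jitter +/-%.2g s, P_app %.3g%%",
              object@noiseSigma, object@timingJitter,
              100 * object@polarization * object@krFraction), "\n")
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d x %d grid, FOV %.1f x %.1f mm\n",
              object@gridShape[1], object@gridShape[2],
              object@fov[1], object@fov[2]))
  cat(sprintf("  fast (alveolar) mode: EV %.4g s, FWHM %.4g s\n",
              object@evFast, object@fwhmFast))
  cat(sprintf("  slow (airway) mode:   EV %.4g s, FWHM %.4g s\n",
              object@evSlow, object@fwhmSlow))
  if (!is.na(object@maa))
    cat(sprintf("  MAA %.3g (ref %.3g), S/V exponent %.2g\n",
                object@maa, object@maaRef, object@svExponent))
  if (object@defectFraction > 0)
    cat(sprintf("  ventilation defects: %.0f%% of parenchyma\n",
                100 * object@defectFraction))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d x %d grid, %d ventilated pixels\n",
              nrow(object@t1Field), ncol(object@t1Field),
              sum(object@roiMask)))
  if (any(object@roiMask))
    cat(sprintf("  T1 range on mask: %.3f - %.3f s\n",
                min(object@t1Field[object@roiMask]),
                max(object@t1Field[object@roiMask])))
})

setMethod("show", "KSpaceSeries", function(object) {
  d <- dim(object@frames[[1]])
  cat(sprintf("KSpaceSeries: %d frames of %d x %d complex samples\n",
              length(object@frames), d[1], d[2]))
  cat("  delays (s):", paste(format(object@delays), collapse = ", "), "\n")
})

setMethod("show", "ImageSeries", function(object) {
  d <- dim(object@frames[[1]])
  cat(sprintf("ImageSeries: %d magnitude frames of %d x %d px (%.3f x %.3f mm)\n",
              length(object@frames), d[1], d[2],
              object@pixelSize[1], object@pixelSize[2]))
  cat("  delays (s):", paste(format(object@delays), collapse = ", "), "\n")
})

setMethod("show", "T1Map", function(object) {
  cat(sprintf("T1Map: %d x %d px, %d in ROI, %d valid (0 < T1 <= %g s)\n",
              nrow(object@t1), ncol(object@t1), sum(object@roi),
              sum(object@mask), object@tmax))
  if (any(object@mask))
    cat(sprintf("  masked T1: median %.3f s, IQR %.3f - %.3f s\n",
                stats::median(object@t1[object@mask]),
                stats::quantile(object@t1[object@mask], 0.25),
                stats::quantile(object@t1[object@mask], 0.75)))
})

setMethod("show", "T1Histogram", function(object) {
  cat(sprintf("T1Histogram: %d bins of %.3g s over [%g, %g] s, %d pixels\n",
              length(object@counts), diff(object@breaks)[1],
              min(object@breaks), max(object@breaks), sum(object@counts)))
})

setMethod("show", "BimodalFit", function(object) {
  if (object@degenerate)
    cat("BimodalFit (degenerate: single mode)\n")
  else cat("BimodalFit\n")
  m <- object@modes
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %s: EV %.4f s, FWHM %.4f s, amplitude %.1f\n",
                m$mode[i], m$ev[i], m$fwhm[i], m$amplitude[i]))
  cat(sprintf("  RMS residual %.3g counts\n", object@residual))
})
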