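#' @import methods
NULL

#' Acquisition parameters for the hyperpolarized-gas VFA FLASH protocol
#'
#' Holds the pulse-sequence timing, matrix size, delay scheme and signal/noise
#' model used by [simulateDelaySeries()]. Defaults reproduce the published
#' protocol: TE = 1.8 ms, TR = 12.6 ms, 64 read x 32 phase-encode matrix,
#' post-inhalation delays \eqn{\tau_d} = 0.2, 0.7, 1.2, 1.7, 2.2 s.
#'
#' @slot te Echo time in seconds.
#' @slot tr Repetition time in seconds (one phase-encode line per TR).
#' @slot nRead Number of frequency-encode (read) samples.
#' @slot nPhase Number of phase-encode lines (equals the number of
#'   excitations of the variable-flip-angle schedule).
#' @slot delays Post-inhalation delays \eqn{\tau_d} in seconds, strictly
#'   increasing.
#' @slot timingJitter Half-width (s) of the zero-mean uniform jitter applied
#'   to each nominal delay, emulating manual-inhalation timing error; 0
#'   disables jitter. The analysis stage always uses the nominal delays.
#' @slot noiseSigma Complex Gaussian k-space noise level, expressed as the
#'   resulting magnitude-image noise standard deviation relative to the peak
#'   noise-free intensity of the shortest-delay frame; 0 disables noise.
#' @slot polarization Nuclear spin polarization P of the krypton, fraction.
#' @slot krFraction Fraction of krypton in the inhaled gas mixture.
#' @slot intraScanDecay Logical; when TRUE each phase-encode line is further
#'   decayed by \eqn{\exp(-t_{line}/T_1)} with \eqn{t_{line}} = line index
#'   times TR (off by default: the protocol was designed to make this decay
#'   negligible).
#' @seealso [acquisitionParams()]
#' @exportClass AcquisitionParams
setClass("AcquisitionParams",
  representation(
    te = "numeric", tr = "numeric",
    nRead = "integer", nPhase = "integer",
    delays = "numeric",
    timingJitter = "numeric", noiseSigma = "numeric",
    polarization = "numeric", krFraction = "numeric",
    intraScanDecay = "logical"
  )
)

setValidity("AcquisitionParams", function(object) {
  msg <- character()
  if (!(object@tr > object@te && object@te > 0))
    msg <- c(msg, "must have tr > te > 0")
  if (object@nRead < 2L || object@nPhase < 2L)
    msg <- c(msg, "matrix dimensions must be >= 2")
  if (length(object@delays) < 1L || any(object@delays <= 0) ||
      is.unsorted(object@delays, strictly = TRUE))
    msg <- c(msg, "delays must be strictly increasing and positive")
  if (object@polarization < 0 || object@polarization > 1)
    msg <- c(msg, "polarization must lie in [0, 1]")
  if (object@krFraction <= 0 || object@krFraction > 1)
    msg <- c(msg, "krFraction must lie in (0, 1]")
  if (object@timingJitter < 0) msg <- c(msg, "timingJitter must be >= 0")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Digital lung phantom specification
#'
#' Describes the stylized 2-D coronal lung phantom: geometry (trachea, two
#' main bronchi, two parenchymal lung fields on a rectangular FOV), the two
#' Gaussian T1 modes (fast = alveolar / high surface-to-volume, slow = airway
#' / low surface-to-volume), optional ventilation defects and the mean
#' alveolar area (MAA) coupling that rescales the parenchymal mode through
#' \eqn{T_1 \propto (MAA)^{svExponent}}.
#'
#' @slot gridShape Integer length-2, image grid in pixels (read x phase).
#' @slot fov Field of view in mm, length-2 (read x phase).
#' @slot evFast,fwhmFast Centre and full width at half maximum (s) of the
#'   fast (alveolar) T1 mode.
#' @slot evSlow,fwhmSlow Centre and FWHM (s) of the slow (airway) T1 mode.
#' @slot maa Mean alveolar area in 1e4 um^2; `NA` leaves the modes as given.
#' @slot maaRef Reference MAA (same units) at which `evFast` applies.
#' @slot svExponent Exponent relating T1 to MAA through the alveolar linear
#'   scale: T1 scales as (maa/maaRef)^svExponent; default 0.5 (linear scale
#'   goes as the square root of an area).
#' @slot defectFraction Fraction of parenchymal pixels assigned to
#'   non-ventilated (zero-signal) circular defect regions.
#' @slot correlationLength Spatial correlation length of the T1 field in
#'   pixels (Gaussian random field); 0 gives pixel-wise independent draws.
#'   Disease-related T1 changes vary regionally rather than pixel to pixel,
#'   and a correlated field also survives the reconstruction point-spread
#'   function instead of being averaged away.
#' @slot seed Integer RNG seed making the phantom reproducible.
#' @seealso [phantomSpec()], [makePhantom()]
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(
    gridShape = "integer", fov = "numeric",
    evFast = "numeric", fwhmFast = "numeric",
    evSlow = "numeric", fwhmSlow = "numeric",
    maa = "numeric", maaRef = "numeric", svExponent = "numeric",
    defectFraction = "numeric", correlationLength = "numeric",
    seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@gridShape) != 2L || any(object@gridShape < 8L))
    msg <- c(msg, "gridShape must be two integers >= 8")
  if (length(object@fov) != 2L || any(object@fov <= 0))
    msg <- c(msg, "fov must be two positive lengths (mm)")
  if (object@evFast <= 0 || object@evSlow <= 0 ||
      object@fwhmFast <= 0 || object@fwhmSlow <= 0)
    msg <- c(msg, "mode centres and widths must be positive")
  if (object@evFast >= object@evSlow)
    msg <- c(msg, "fast (alveolar) mode centre must be below slow (airway) mode centre")
  if (!is.na(object@maa) && object@maa <= 0)
    msg <- c(msg, "maa must be positive")
  if (object@defectFraction < 0 || object@defectFraction > 1)
    msg <- c(msg, "defectFraction must lie in [0, 1]")
  if (object@correlationLength < 0)
    msg <- c(msg, "correlationLength must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Ground-truth fields of a simulated lung
#'
#' Per-pixel truth produced by [makePhantom()]: the T1 field (s), the initial
#' hyperpolarized signal amplitude m0 (zero outside the ventilated domain and
#' inside defect regions), the ventilated-region mask and the label field
#' distinguishing airway from parenchyma.
#'
#' @slot t1Field Numeric matrix of T1 values (s); positive wherever
#'   `roiMask` is TRUE.
#' @slot m0Field Non-negative numeric matrix of initial signal amplitudes.
#' @slot roiMask Logical matrix: TRUE for ventilated pixels with signal.
#' @slot labels Integer matrix: 0 background, 1 parenchyma, 2 airway.
#' @slot fov Field of view in mm (read x phase).
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(
    t1Field = "matrix", m0Field = "matrix", roiMask = "matrix",
    labels = "matrix", fov = "numeric"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  dims <- dim(object@t1Field)
  if (!identical(dims, dim(object@m0Field)) ||
      !identical(dims, dim(object@roiMask)))
    msg <- c(msg, "t1Field, m0Field and roiMask must share dimensions")
  if (any(object@m0Field < 0)) msg <- c(msg, "m0Field must be non-negative")
  if (any(object@t1Field[object@roiMask] <= 0))
    msg <- c(msg, "t1Field must be positive on the ventilated mask")
  if (length(msg)) msg else TRUE
})

#' Delay series of complex k-space frames
#'
#' One raw k-space frame per post-inhalation delay, as produced by
#' [simulateDelaySeries()]. The k-space origin (DC) sits at the grid centre
#' (index `floor(n/2) + 1` per dimension).
#'
#' @slot frames List of complex matrices, all the same size.
#' @slot delays Nominal delays \eqn{\tau_d} (s), strictly increasing.
#' @slot actualDelays Delays actually realised after timing jitter; equal to
#'   `delays` when jitter is off. Analysis always uses the nominal values.
#' @slot fov Field of view in mm.
#' @exportClass KSpaceSeries
setClass("KSpaceSeries",
  representation(frames = "list", delays = "numeric",
                 actualDelays = "numeric", fov = "numeric")
)

#' Delay series of reconstructed magnitude images
#'
#' @slot frames List of non-negative numeric matrices, all the same size.
#' @slot delays Nominal delays \eqn{\tau_d} (s), strictly increasing.
#' @slot fov Field of view in mm.
#' @slot pixelSize Pixel size in mm (fov / reconstructed grid).
#' @exportClass ImageSeries
setClass("ImageSeries",
  representation(frames = "list", delays = "numeric", fov = "numeric",
                 pixelSize = "numeric")
)

.validateSeries <- function(object, complexOK) {
  msg <- character()
  n <- length(object@frames)
  if (n < 1L) msg <- c(msg, "series must contain at least one frame")
  if (length(object@delays) != n)
    msg <- c(msg, "delays must match the number of frames")
  if (n && (any(object@delays <= 0) ||
            is.unsorted(object@delays, strictly = TRUE)))
    msg <- c(msg, "delays must be strictly increasing and positive")
  dims <- lapply(object@frames, dim)
  if (n && !all(vapply(dims, identical, logical(1), dims[[1]])))
    msg <- c(msg, "all frames must share dimensions")
  if (n && !complexOK && any(vapply(object@frames,
                                    function(f) any(f < 0), logical(1))))
    msg <- c(msg, "magnitude frames must be non-negative")
  if (length(msg)) msg else TRUE
}

setValidity("KSpaceSeries", function(object) .validateSeries(object, TRUE))
setValidity("ImageSeries", function(object) .validateSeries(object, FALSE))

#' Pixel-wise T1 map with validity mask
#'
#' Result of [buildT1Map()]: per-pixel T1 and amplitude estimates from
#' mono-exponential fits \eqn{S(\tau_d) = S_0 \exp(-\tau_d/T_1)}, together
#' with the region of interest and the final validity mask. A pixel is valid
#' when its fit converged, its T1 lies in the physically meaningful range
#' \eqn{0 < T_1 \le} `tmax` (6 s by default) and it falls inside the ROI.
#'
#' @slot t1 Numeric matrix of fitted T1 (s); NA where no fit was attempted
#'   or the fit failed.
#' @slot s0 Numeric matrix of fitted amplitudes.
#' @slot mask Logical matrix of valid pixels (subset of `roi`).
#' @slot roi Logical matrix, the lung-contour region of interest.
#' @slot tmax Upper T1 acceptance bound in seconds (inclusive).
#' @slot fov Field of view in mm.
#' @exportClass T1Map
setClass("T1Map",
  representation(t1 = "matrix", s0 = "matrix", mask = "matrix",
                 roi = "matrix", tmax = "numeric", fov = "numeric")
)

setValidity("T1Map", function(object) {
  msg <- character()
  if (!identical(dim(object@t1), dim(object@mask)) ||
      !identical(dim(object@t1), dim(object@roi)))
    msg <- c(msg, "t1, mask and roi must share dimensions")
  if (any(object@mask & !object@roi))
    msg <- c(msg, "mask must be a subset of roi")
  tv <- object@t1[object@mask]
  if (any(!is.finite(tv)) || any(tv <= 0) ||
      any(tv > object@tmax * (1 + 1e-9)))
    msg <- c(msg, sprintf("masked T1 values must satisfy 0 < T1 <= %g", object@tmax))
  if (length(msg)) msg else TRUE
})

#' Binned T1 histogram
#'
#' Fixed-scheme histogram of masked T1 values: 200 intervals of 0.03 s,
#' spanning exactly the 0--6 s acceptance window. Values falling exactly on a
#' bin edge are assigned to the lower bin, matching the inclusive upper bound
#' of the T1 range filter.
#'
#' @slot breaks Bin edges in s (length nBins + 1, starting at 0).
#' @slot counts Non-negative integer pixel frequencies (length nBins).
#' @seealso [binT1()], [fitBimodal()], [poolHistograms()]
#' @exportClass T1Histogram
setClass("T1Histogram",
  representation(breaks = "numeric", counts = "numeric")
)

setValidity("T1Histogram", function(object) {
  msg <- character()
  nb <- length(object@counts)
  if (length(object@breaks) != nb + 1L)
    msg <- c(msg, "breaks must have length(counts) + 1 entries")
  w <- diff(object@breaks)
  if (any(abs(w - w[1]) > 1e-9)) msg <- c(msg, "bin width must be constant")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Bimodal Gaussian decomposition of a T1 histogram
#'
#' Result of [fitBimodal()]: up to two Gaussian components
#' \eqn{A_m \exp(-(T_1-\mu_m)^2/(2\sigma_m^2))} fitted to bin-centre counts.
#' The mode with the smaller centre is labelled `fast` (alveolar), the other
#' `slow` (airway). `ev` is the mode centre (the expected value biomarker),
#' `fwhm` the full width at half maximum \eqn{2\sqrt{2\ln 2}\,\sigma}.
#'
#' @slot modes data.frame with one row per mode and columns `mode`
#'   ("fast"/"slow"), `ev`, `fwhm`, `amplitude`.
#' @slot degenerate TRUE when automated peak picking found fewer than two
#'   modes and a single Gaussian was fitted instead.
#' @slot residual Root-mean-square fit residual in counts.
#' @slot fitted Fitted model curve at bin centres (for histogram overlays).
#' @slot histogram The input [T1Histogram-class].
#' @exportClass BimodalFit
setClass("BimodalFit",
  representation(modes = "data.frame", degenerate = "logical",
                 residual = "numeric", fitted = "numeric",
                 histogram = "T1Histogram")
)

setValidity("BimodalFit", function(object) {
  msg <- character()
  m <- object@modes
  need <- c("mode", "ev", "fwhm", "amplitude")
  if (!all(need %in% names(m)))
    msg <- c(msg, "modes must have columns mode, ev, fwhm, amplitude")
  else {
    if (any(m$fwhm <= 0) || any(m$amplitude <= 0))
      msg <- c(msg, "mode widths and amplitudes must be positive")
    if (nrow(m) == 2L && m$ev[m$mode == "fast"] >= m$ev[m$mode == "slow"])
      msg <- c(msg, "fast mode centre must be below slow mode centre")
    if (!object@degenerate && nrow(m) != 2L)
      msg <- c(msg, "non-degenerate fits must have exactly two modes")
  }
  if (length(msg)) msg else TRUE
})
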