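#' Apparent spin polarization of a hyperpolarized gas mixture
#'
#' The apparent polarization is the nuclear spin polarization P of the
#' krypton multiplied by the fraction of krypton in the inhaled gas mixture;
#' it is the polarization that matters for the available imaging signal when
#' the hyperpolarized isotope cannot be separated from the buffer gas.
#'
#' @param p Nuclear spin polarization, fraction in `[0, 1]`.
#' @param xKr Krypton fraction of the mixture, in `(0, 1]`.
#' @return The apparent polarization `p * xKr`, a fraction.
#' @examples
#' ## 16.5% polarization of a 15% Kr / 85% N2 mixture
#' apparentPolarization(0.165, 0.15)   # ~0.025
#' @export
apparentPolarization <- function(p, xKr) {
  stopifnot(is.numeric(p), is.numeric(xKr))
  if (any(p < 0 | p > 1)) stop("polarization must lie in [0, 1]")
  if (any(xKr <= 0 | xKr > 1)) stop("krypton fraction must lie in (0, 1]")
  p * xKr
}

#' Variable flip angle schedule for hyperpolarized FLASH
#'
#' Hyperpolarized magnetization is non-renewable: each excitation consumes
#' part of it. The schedule \eqn{\theta_j = \arctan(1/\sqrt{n-j})},
#' \eqn{j = 1, \dots, n} (so \eqn{\theta_n = 90^\circ}) makes the transverse
#' signal \eqn{\sin\theta_j \prod_{i<j} \cos\theta_i = 1/\sqrt{n}} identical
#' for every k-space line, in the absence of relaxation.
#'
#' @param n Number of excitations (phase-encode lines), `>= 1`.
#' @return Flip angles in radians, length `n`, ending at `pi/2`.
#' @examples
#' vfaSchedule(1)                 # 90 degrees
#' vfaSchedule(32)[1] * 180 / pi  # ~10.18 degrees
#' @export
vfaSchedule <- function(n) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L)
    stop("n must be a single integer >= 1")
  j <- seq_len(n)
  atan(1 / sqrt(n - j))
}

#' T1 from surface-to-volume ratio under surface relaxation
#'
#' Surface quadrupolar relaxation shortens the gas-phase T1 in proportion to
#' the surface available per unit gas volume: \eqn{T_1 = \kappa \cdot V/S},
#' i.e. `kappa / sv`. Larger alveoli (emphysema) mean lower S/V and longer T1.
#'
#' @param sv Surface-to-volume ratio field (any positive units).
#' @param kappa Calibration constant in s times the S/V unit.
#' @return T1 in seconds, same shape as `sv`.
#' @seealso [svFromMAA()] for the mean-alveolar-area coupling.
#' @export
t1FromSV <- function(sv, kappa) {
  if (any(!is.finite(sv)) || any(sv <= 0))
    stop("surface-to-volume ratio must be positive and finite")
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0)
    stop("kappa must be a single positive number")
  kappa / sv
}

#' Surface-to-volume ratio implied by mean alveolar area
#'
#' The alveolar linear scale grows as the square root of the mean alveolar
#' area (MAA), and S/V falls inversely with the linear scale, so
#' \eqn{S/V \propto MAA^{-e}} with `exponent` e = 0.5 by default. Combined
#' with [t1FromSV()] this gives \eqn{T_1 \propto MAA^{e}}.
#'
#' @param maa Mean alveolar area (e.g. 1e4 um^2), positive.
#' @param svRef S/V at the reference MAA.
#' @param maaRef Reference mean alveolar area, same units as `maa`.
#' @param exponent Scaling exponent, default 0.5.
#' @return Surface-to-volume ratio, same units as `svRef`.
#' @export
svFromMAA <- function(maa, svRef, maaRef, exponent = 0.5) {
  if (any(maa <= 0) || any(maaRef <= 0) || any(svRef <= 0))
    stop("maa, maaRef and svRef must be positive")
  svRef * (maa / maaRef)^(-exponent)
}

# Published group-level mode parameters used as phantom presets: for each
# group the mean and between-lung SD of the four biomarkers (s).
.modePresets <- list(
  control = list(
    evFast = 1.00620, fwhmFast = 0.14576,
    evSlow = 1.2699,  fwhmSlow = 0.44011,
    sdEvFast = 0.009, sdFwhmFast = 0.053,
    sdEvSlow = 0.075, sdFwhmSlow = 0.124
  ),
  elastase = list(
    evFast = 1.25358, fwhmFast = 0.23361,
    evSlow = 1.7009,  fwhmSlow = 0.55138,
    sdEvFast = 0.088, sdFwhmFast = 0.079,
    sdEvSlow = 0.249, sdFwhmSlow = 0.167
  )
)

#' Preset T1-mode parameters for the two study groups
#'
#' Group-average expected values (EV) and full widths at half maximum (FWHM)
#' of the fast (alveolar) and slow (airway) T1 modes, with the between-lung
#' standard deviations, for healthy control lungs and for the
#' elastase-induced emphysema model. These drive [phantomSpec()] presets and
#' the per-lung variability in [runExperiment()].
#'
#' @param group `"control"` or `"elastase"`.
#' @return Named list with elements `evFast`, `fwhmFast`, `evSlow`,
#'   `fwhmSlow` and their between-lung SDs `sdEvFast`, etc. (all seconds).
#' @export
modePresets <- function(group = c("control", "elastase")) {
  .modePresets[[match.arg(group)]]
}

#' Construct a digital lung phantom specification
#'
#' @param preset `"control"` or `"elastase"`: initialises the two T1 modes
#'   from the corresponding group averages (see [modePresets()]). Individual
#'   mode parameters may be overridden.
#' @param gridShape Image grid in pixels (read x phase), default 64 x 64.
#' @param fov Field of view in mm, default `c(50.9, 40.7)`.
#' @param evFast,fwhmFast,evSlow,fwhmSlow Mode centres and widths (s);
#'   defaults come from `preset`.
#' @param maa Mean alveolar area (1e4 um^2). When given, the fast (alveolar)
#'   mode is rescaled by `(maa / maaRef)^svExponent`, the T1 change implied
#'   by the surface-to-volume law; `NA` (default) leaves the modes as given.
#' @param maaRef Reference MAA at which `evFast` applies (default 2.7, a
#'   healthy-lung value).
#' @param svExponent Exponent of the MAA coupling, default 0.5.
#' @param defectFraction Fraction of parenchymal pixels assigned to
#'   non-ventilated defect regions, default 0.
#' @param correlationLength Spatial correlation length of the T1 field in
#'   pixels, default 3; 0 gives independent per-pixel draws.
#' @param seed Integer seed for the per-pixel T1 draws and defect placement.
#' @return A [PhantomSpec-class].
#' @examples
#' spec <- phantomSpec("control", seed = 1)
#' gt <- makePhantom(spec)
#' @export
phantomSpec <- function(preset = c("control", "elastase"),
                        gridShape = c(64L, 64L), fov = c(50.9, 40.7),
                        evFast = NULL, fwhmFast = NULL,
                        evSlow = NULL, fwhmSlow = NULL,
                        maa = NA_real_, maaRef = 2.7, svExponent = 0.5,
                        defectFraction = 0, correlationLength = 3,
                        seed = 1L) {
  pr <- modePresets(match.arg(preset))
  new("PhantomSpec",
      gridShape = as.integer(gridShape), fov = as.numeric(fov),
      evFast = evFast %||% pr$evFast, fwhmFast = fwhmFast %||% pr$fwhmFast,
      evSlow = evSlow %||% pr$evSlow, fwhmSlow = fwhmSlow %||% pr$fwhmSlow,
      maa = as.numeric(maa), maaRef = maaRef, svExponent = svExponent,
      defectFraction = defectFraction,
      correlationLength = correlationLength, seed = as.integer(seed))
}

# standard-normal Gaussian random field with periodic Gaussian correlation
# of length L pixels; exact unit marginal variance by construction
.correlatedField <- function(nr, nc, L) {
  w <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (L <= 0) return(w)
  dr <- pmin(0:(nr - 1), nr - (0:(nr - 1)))
  dc <- pmin(0:(nc - 1), nc - (0:(nc - 1)))
  g <- exp(-outer(dr^2, dc^2, `+`) / (2 * L^2))
  g <- g / sum(g)
  conv <- Re(stats::fft(stats::fft(w) * stats::fft(g), inverse = TRUE)) /
    (nr * nc)
  conv / sqrt(sum(g^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate expr under a temporary RNG state seeded with `seed`
.withSeed <- function(seed, expr) {
  if (is.na(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  eval.parent(substitute(expr))
}

# stylized coronal geometry in grid-fraction coordinates
.phantomMasks <- function(gridShape) {
  nr <- gridShape[1]; nc <- gridShape[2]
  r <- (row(matrix(0, nr, nc)) - 0.5) / nr
  c_ <- (col(matrix(0, nr, nc)) - 0.5) / nc

  ellipse <- function(r0, c0, ar, ac)
    ((r - r0) / ar)^2 + ((c_ - c0) / ac)^2 <= 1
  lungs <- ellipse(0.60, 0.29, 0.32, 0.17) | ellipse(0.60, 0.71, 0.32, 0.17)

  # trachea ~3.5 mm across on a ~41 mm FOV
  trachea <- r >= 0.04 & r <= 0.42 & abs(c_ - 0.5) <= 0.042

  segDist <- function(p1, p2) {
    v <- p2 - p1
    t <- pmin(1, pmax(0, ((r - p1[1]) * v[1] + (c_ - p1[2]) * v[2]) /
                           sum(v^2)))
    sqrt((r - (p1[1] + t * v[1]))^2 + (c_ - (p1[2] + t * v[2]))^2)
  }
  # the images are non-slice-selective projections, so the hilar/central
  # zones around the bronchial tree are airway-dominated over an extended
  # area: main-stem bronchi plus lobar branches, drawn wide
  bronchi <- segDist(c(0.42, 0.50), c(0.62, 0.31)) <= 0.045 |
             segDist(c(0.42, 0.50), c(0.62, 0.69)) <= 0.045 |
             segDist(c(0.62, 0.31), c(0.82, 0.26)) <= 0.035 |
             segDist(c(0.62, 0.69), c(0.82, 0.74)) <= 0.035 |
             segDist(c(0.58, 0.34), c(0.76, 0.44)) <= 0.028 |
             segDist(c(0.58, 0.66), c(0.76, 0.56)) <= 0.028 |
             segDist(c(0.50, 0.42), c(0.60, 0.20)) <= 0.022 |
             segDist(c(0.50, 0.58), c(0.60, 0.80)) <= 0.022

  airway <- trachea | bronchi
  parenchyma <- lungs & !airway
  list(airway = airway, parenchyma = parenchyma)
}

#' Generate ground-truth T1 and signal fields from a phantom specification
#'
#' Builds a stylized 2-D coronal lung: a trachea and two main bronchi (low
#' surface-to-volume, hence long T1 drawn from the slow mode) over two
#' parenchymal lung fields (high S/V, short T1 drawn from the fast mode).
#' Per-pixel T1 values are sampled from the two Gaussian modes of the
#' specification; non-ventilated defect regions receive zero signal.
#' Deterministic for a fixed specification (the seed lives in the spec).
#'
#' @param spec A [PhantomSpec-class].
#' @return A [GroundTruth-class] with T1 field (s), m0 field, ventilated
#'   mask and airway/parenchyma labels.
#' @export
makePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  masks <- .phantomMasks(spec@gridShape)
  if (!any(masks$parenchyma)) stop("phantom has an empty parenchyma mask")

  evFast <- spec@evFast; fwhmFast <- spec@fwhmFast
  if (!is.na(spec@maa)) {
    s <- (spec@maa / spec@maaRef)^spec@svExponent
    evFast <- evFast * s
    fwhmFast <- fwhmFast * s
  }
  toSigma <- 1 / (2 * sqrt(2 * log(2)))

  .withSeed(spec@seed, {
    t1 <- matrix(0, spec@gridShape[1], spec@gridShape[2])
    nP <- sum(masks$parenchyma); nA <- sum(masks$airway)
    z <- .correlatedField(spec@gridShape[1], spec@gridShape[2],
                          spec@correlationLength)
    t1[masks$parenchyma] <- pmax(0.05,
      evFast + fwhmFast * toSigma * z[masks$parenchyma])
    t1[masks$airway] <- pmax(0.05,
      spec@evSlow + spec@fwhmSlow * toSigma * z[masks$airway])

    ventilated <- masks$parenchyma | masks$airway
    m0 <- matrix(0, spec@gridShape[1], spec@gridShape[2])
    m0[ventilated] <- 1

    if (spec@defectFraction >= 1) {
      m0[] <- 0
    } else if (spec@defectFraction > 0) {
      target <- spec@defectFraction * nP
      idx <- which(masks$parenchyma, arr.ind = TRUE)
      radius <- max(2, round(0.08 * min(spec@gridShape)))
      killed <- matrix(FALSE, spec@gridShape[1], spec@gridShape[2])
      guard <- 0L
      while (sum(killed & masks$parenchyma) < target && guard < 100L) {
        ctr <- idx[sample.int(nrow(idx), 1L), ]
        d2 <- (row(m0) - ctr[1])^2 + (col(m0) - ctr[2])^2
        killed <- killed | d2 <= radius^2
        guard <- guard + 1L
      }
      m0[killed] <- 0
    }

    labels <- matrix(0L, spec@gridShape[1], spec@gridShape[2])
    labels[masks$parenchyma] <- 1L
    labels[masks$airway] <- 2L
    new("GroundTruth", t1Field = t1, m0Field = m0,
        roiMask = ventilated & m0 > 0, labels = labels, fov = spec@fov)
  })
}

#' Construct acquisition parameters
#'
#' Defaults reproduce the published single-inhalation VFA FLASH protocol:
#' TE 1.8 ms, TR 12.6 ms, 64 read x 32 phase-encode matrix, delays
#' 0.2--2.2 s in 0.5 s steps, nuclear spin polarization 16.5% and krypton
#' fraction 0.15 (apparent polarization ~2.5%). `noiseSigma = 0.02` gives a
#' peak-signal SNR of 50 in the shortest-delay frame. An alternative
#' four-delay scheme `c(0.5, 1, 1.5, 2)` was also in protocol use and can
#' be passed via `delays`. The protocol tolerated a manual-inhalation
#' timing error of about +/-0.2 s; set `timingJitter = 0.2` to emulate it
#' in sensitivity studies (off by default, because the cohort generator
#' already draws per-lung variability at the observed between-lung level
#' and independent per-frame jitter would double-count it).
#'
#' @param te,tr Echo and repetition time (s).
#' @param nRead,nPhase Acquisition matrix (read x phase).
#' @param delays Post-inhalation delays (s), strictly increasing.
#' @param timingJitter Half-width (s) of the uniform timing jitter; 0 = off.
#' @param noiseSigma Magnitude-noise SD relative to peak signal; 0 = off.
#' @param polarization Nuclear spin polarization, fraction.
#' @param krFraction Krypton fraction of the gas mixture.
#' @param intraScanDecay Model T1 decay across the phase-encode train.
#' @return An [AcquisitionParams-class].
#' @export
acquisitionParams <- function(te = 0.0018, tr = 0.0126,
                              nRead = 64L, nPhase = 32L,
                              delays = c(0.2, 0.7, 1.2, 1.7, 2.2),
                              timingJitter = 0, noiseSigma = 0.02,
                              polarization = 0.165, krFraction = 0.15,
                              intraScanDecay = FALSE) {
  new("AcquisitionParams", te = te, tr = tr,
      nRead = as.integer(nRead), nPhase = as.integer(nPhase),
      delays = as.numeric(delays),
      timingJitter = timingJitter, noiseSigma = noiseSigma,
      polarization = polarization, krFraction = krFraction,
      intraScanDecay = intraScanDecay)
}

#' Simulate a T1-weighted delay series of k-space frames
#'
#' For each post-inhalation delay \eqn{\tau_d}, a fresh batch of
#' hyperpolarized gas is inhaled and one VFA FLASH image is acquired, so the
#' available magnetization at acquisition is
#' \eqn{m_0 \exp(-\tau_d / T_1)} per pixel, scaled by the apparent
#' polarization and by the \eqn{1/\sqrt{n}} per-line yield of the
#' variable-flip-angle schedule. The image-domain signal is Fourier
#' transformed (unitary, centred) and the central `nRead x nPhase` block is
#' kept, emulating the acquisition matrix; complex Gaussian noise added in
#' k-space yields Rician magnitude noise after reconstruction. With
#' `intraScanDecay = TRUE` each phase-encode line `p` (acquired at
#' `t = (p-1) * tr`) is further decayed by `exp(-t/T1)`. Timing jitter
#' perturbs the realised delay; the stored nominal delays are what the
#' analysis uses, reproducing the accepted manual-inhalation timing error.
#'
#' @param gt A [GroundTruth-class].
#' @param acq An [AcquisitionParams-class]; the acquisition matrix must not
#'   exceed the phantom grid.
#' @param seed Integer seed for jitter and noise draws; `NA` uses the
#'   current RNG state.
#' @return A [KSpaceSeries-class], one frame per delay.
#' @examples
#' gt <- makePhantom(phantomSpec("control", seed = 1))
#' ks <- simulateDelaySeries(gt, acquisitionParams(noiseSigma = 0,
#'                                                 timingJitter = 0), seed = 1)
#' @export
simulateDelaySeries <- function(gt, acq = acquisitionParams(), seed = NA_integer_) {
  stopifnot(is(gt, "GroundTruth"), is(acq, "AcquisitionParams"))
  validObject(gt); validObject(acq)
  nr <- nrow(gt@t1Field); nc <- ncol(gt@t1Field)
  if (acq@nRead > nr || acq@nPhase > nc)
    stop("acquisition matrix exceeds the phantom grid")

  papp <- apparentPolarization(acq@polarization, acq@krFraction)
  lineScale <- 1 / sqrt(acq@nPhase)
  live <- gt@m0Field > 0
  rate <- matrix(0, nr, nc)
  rate[live] <- 1 / gt@t1Field[live]   # decay rate; 0 where no signal

  signalAt <- function(tau) {
    s <- matrix(0, nr, nc)
    s[live] <- papp * lineScale * gt@m0Field[live] * exp(-tau * rate[live])
    s
  }
  rows <- .centreBlock(nr, acq@nRead)
  cols <- .centreBlock(nc, acq@nPhase)
  sigmaAbs <- acq@noiseSigma * max(signalAt(acq@delays[1]), 0)

  .withSeed(seed, {
    actual <- acq@delays
    if (acq@timingJitter > 0)
      actual <- pmax(0, actual + stats::runif(length(actual),
                                              -acq@timingJitter,
                                              acq@timingJitter))
    frames <- lapply(actual, function(tau) {
      if (acq@intraScanDecay) {
        k <- matrix(0 + 0i, acq@nRead, acq@nPhase)
        for (p in seq_len(acq@nPhase)) {
          s <- signalAt(tau)
          extra <- matrix(1, nr, nc)
          extra[live] <- exp(-(p - 1) * acq@tr * rate[live])
          kf <- kspaceFromImage(s * extra)
          k[, p] <- kf[rows, cols[p]]
        }
      } else {
        k <- kspaceFromImage(signalAt(tau))[rows, cols]
      }
      if (sigmaAbs > 0)
        k <- k + complex(real = stats::rnorm(length(k), 0, sigmaAbs),
                         imaginary = stats::rnorm(length(k), 0, sigmaAbs))
      k
    })
    new("KSpaceSeries", frames = frames, delays = acq@delays,
        actualDelays = actual, fov = gt@fov)
  })
}
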