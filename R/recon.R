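#' Sine-bell squared apodization
#'
#' Multiplies a k-space frame by the separable window
#' \eqn{w(k) = \sin^2(\pi (k + 1/2) / N)}, \eqn{k = 0, \dots, N-1}, in each
#' dimension. The half-sample offset makes the window exactly symmetric
#' (`w[k] == w[N-1-k]`) with no zeroed sample at the acquired edges; the
#' window tapers the high spatial frequencies and suppresses truncation
#' (Gibbs) ringing at the cost of spatial resolution.
#'
#' @param frame Complex or numeric matrix of k-space samples.
#' @return Matrix of the same shape with the window applied.
#' @export
apodizeSineBellSquared <- function(frame) {
  if (!is.matrix(frame) || any(dim(frame) < 2L))
    stop("frame must be a matrix with both dimensions >= 2")
  wr <- sineBellSquared(nrow(frame))
  wc <- sineBellSquared(ncol(frame))
  frame * outer(wr, wc)
}

#' @rdname apodizeSineBellSquared
#' @param n Window length.
#' @return `sineBellSquared(n)` returns the length-`n` window itself.
#' @export
sineBellSquared <- function(n) {
  k <- seq_len(n) - 1
  sin(pi * (k + 0.5) / n)^2
}

#' Centred zero filling of k-space
#'
#' Embeds a k-space frame in a larger zero-padded grid with the DC sample
#' kept at the grid centre, interpolating the reconstructed image onto a
#' finer pixel grid without adding information. The sample energy
#' (sum of squared moduli) is unchanged.
#'
#' @param frame Complex or numeric k-space matrix.
#' @param target Integer length-2, target grid size; each must be at least
#'   the corresponding source dimension.
#' @return Matrix of size `target`.
#' @export
zeroFill <- function(frame, target) {
  target <- as.integer(target)
  if (length(target) != 2L || any(target < dim(frame)))
    stop("target dimensions must be >= source dimensions")
  out <- matrix(if (is.complex(frame)) 0 + 0i else 0, target[1], target[2])
  out[.centreBlock(target[1], nrow(frame)),
      .centreBlock(target[2], ncol(frame))] <- frame
  out
}

#' Reconstruct a magnitude image from one k-space frame
#'
#' The reconstruction chain: optional truncation of the frame to its central
#' block, sine-bell squared apodization, centred zero filling to the target
#' grid, unitary inverse 2-D Fourier transform, elementwise modulus. With
#' the default 64-point target and a 50.9 x 40.7 mm field of view the pixel
#' size is 0.795 x 0.635 mm.
#'
#' @param frame Complex k-space matrix (DC at the grid centre).
#' @param fov Field of view in mm, length 2.
#' @param target Reconstructed grid size, default `c(64, 64)`.
#' @param apodize Apply the sine-bell squared window (default TRUE).
#' @param truncateTo Optional length-2 integer: crop the frame to this
#'   central block before apodization (use `NA` to keep a dimension). Allows
#'   processing a 64-point read dimension as acquired, or truncated to 32
#'   points as in the published processing chain.
#' @return A list with `image` (non-negative matrix of size `target`) and
#'   `pixelSize` (mm).
#' @seealso [reconstructSeries()]
#' @export
reconstructFrame <- function(frame, fov, target = c(64L, 64L),
                             apodize = TRUE, truncateTo = NULL) {
  if (!is.matrix(frame) || any(dim(frame) < 2L))
    stop("frame must be a matrix with both dimensions >= 2")
  if (!is.null(truncateTo)) {
    tt <- ifelse(is.na(truncateTo), dim(frame), as.integer(truncateTo))
    if (any(tt > dim(frame)))
      stop("truncateTo must not exceed the frame dimensions")
    frame <- frame[.centreBlock(nrow(frame), tt[1]),
                   .centreBlock(ncol(frame), tt[2]), drop = FALSE]
  }
  if (apodize) frame <- apodizeSineBellSquared(frame)
  k <- zeroFill(frame, target)
  img <- Mod(imageFromKspace(k))
  list(image = img, pixelSize = fov / as.integer(target))
}

#' @describeIn reconstructSeries Reconstruct every frame of a k-space
#'   series; all frames share the options.
#' @param target Reconstructed grid size, default `c(64, 64)`.
#' @param apodize Apply the sine-bell squared window (default TRUE).
#' @param truncateTo Optional central-block truncation before apodization
#'   (see [reconstructFrame()]).
#' @export
setMethod("reconstructSeries", "KSpaceSeries",
  function(object, target = c(64L, 64L), apodize = TRUE, truncateTo = NULL) {
    rec <- lapply(object@frames, reconstructFrame, fov = object@fov,
                  target = target, apodize = apodize, truncateTo = truncateTo)
    new("ImageSeries",
        frames = lapply(rec, `[[`, "image"),
        delays = object@delays, fov = object@fov,
        pixelSize = rec[[1]]$pixelSize)
  })
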