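# Centred, unitary 2-D DFT helpers. Convention used throughout: the k-space
# origin (DC) sits at index floor(n/2) + 1 in each dimension, i.e. matrices
# are stored fftshift-ed, and the transforms are normalized by 1/sqrt(N*M) so
# that Parseval's identity holds exactly in both directions.

.fftshiftIdx <- function(n, inverse = FALSE) {
  s <- if (inverse) ceiling(n / 2) else floor(n / 2)
  c(seq_len(n)[-seq_len(s)], seq_len(s))
}

fftshift2 <- function(x, inverse = FALSE) {
  x[.fftshiftIdx(nrow(x), inverse), .fftshiftIdx(ncol(x), inverse)]
}

# image (centred) -> k-space (centred), unitary
kspaceFromImage <- function(img) {
  fftshift2(stats::fft(fftshift2(img, inverse = TRUE))) /
    sqrt(length(img))
}

# k-space (centred) -> complex image (centred), unitary
imageFromKspace <- function(k) {
  fftshift2(stats::fft(fftshift2(k, inverse = TRUE), inverse = TRUE)) /
    sqrt(length(k))
}

# indices of the centred m-sample block within an n-sample dimension,
# chosen so the DC sample (floor(n/2)+1) maps onto floor(m/2)+1
.centreBlock <- function(n, m) {
  if (m > n) stop("block larger than dimension")
  start <- floor(n / 2) - floor(m / 2) + 1L
  seq.int(start, start + m - 1L)
}
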