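#' Write a delay series to NIfTI frames with a delay sidecar
#'
#' Each frame is written as one NIfTI file (`frame_001.nii.gz`, ...) with
#' the pixel size recorded in its header; the delays go to a sidecar
#' `delays.csv` with columns `frame_index`, `tau_d_s`. Complex k-space
#' frames are written as paired `_real` / `_imag` NIfTI files.
#'
#' @param series An [ImageSeries-class] or [KSpaceSeries-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeDelaySeries <- function(series, dir) {
  stopifnot(is(series, "ImageSeries") || is(series, "KSpaceSeries"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(series@frames[[1]])
  pix <- series@fov / d
  paths <- character()
  for (i in seq_along(series@frames)) {
    f <- series@frames[[i]]
    stem <- file.path(dir, sprintf("frame_%03d", i))
    if (is.complex(f)) {
      pr <- paste0(stem, "_real.nii.gz"); pi <- paste0(stem, "_imag.nii.gz")
      RNifti::writeNifti(RNifti::asNifti(Re(f), pixdim = pix), pr)
      RNifti::writeNifti(RNifti::asNifti(Im(f), pixdim = pix), pi)
      paths <- c(paths, pr, pi)
    } else {
      p <- paste0(stem, ".nii.gz")
      RNifti::writeNifti(RNifti::asNifti(f, pixdim = pix), p)
      paths <- c(paths, p)
    }
  }
  csv <- file.path(dir, "delays.csv")
  utils::write.csv(data.frame(frame_index = seq_along(series@frames),
                              tau_d_s = series@delays),
                   csv, row.names = FALSE)
  invisible(c(paths, csv))
}

#' Read and validate a delay-time sidecar table
#'
#' @param path CSV file with columns `frame_index`, `tau_d_s`.
#' @return data.frame, validated: numeric, positive, strictly increasing
#'   delays. A malformed row is reported by number.
#' @export
readDelayTable <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("frame_index", "tau_d_s") %in% names(tab)))
    stop("delay table must have columns frame_index, tau_d_s: ", path)
  bad <- which(!is.finite(suppressWarnings(as.numeric(tab$tau_d_s))) |
                 suppressWarnings(as.numeric(tab$tau_d_s)) <= 0)
  if (length(bad))
    stop("invalid delay in row ", bad[1], " of ", path)
  tab$tau_d_s <- as.numeric(tab$tau_d_s)
  if (is.unsorted(tab$tau_d_s, strictly = TRUE))
    stop("delays must be strictly increasing in ", path)
  tab
}

#' Read a magnitude delay series from NIfTI frames and a delay sidecar
#'
#' Counterpart of [writeDelaySeries()] for magnitude images.
#'
#' @param dir Directory containing `frame_*.nii.gz` files and `delays.csv`.
#' @param fov Field of view in mm; by default recovered from the NIfTI
#'   pixel size and matrix.
#' @return An [ImageSeries-class].
#' @export
readImageSeries <- function(dir, fov = NULL) {
  files <- sort(list.files(dir, "^frame_[0-9]+\\.nii(\\.gz)?$",
                           full.names = TRUE))
  if (length(files) == 0L) stop("no frame NIfTI files found in ", dir)
  tab <- readDelayTable(file.path(dir, "delays.csv"))
  if (nrow(tab) != length(files))
    stop("delay table rows do not match the number of frames in ", dir)
  imgs <- lapply(files, function(p) {
    a <- RNifti::readNifti(p)
    matrix(as.numeric(a), dim(a)[1], dim(a)[2])
  })
  if (is.null(fov)) {
    hdr <- RNifti::niftiHeader(RNifti::readNifti(files[1]))
    fov <- hdr$pixdim[2:3] * dim(imgs[[1]])
  }
  new("ImageSeries", frames = imgs, delays = tab$tau_d_s,
      fov = as.numeric(fov),
      pixelSize = as.numeric(fov) / dim(imgs[[1]]))
}

#' Write a T1 map to NIfTI and CSV
#'
#' Writes `t1.nii.gz` (NA outside fitted pixels encoded as 0), `mask.nii.gz`
#' and a `t1_pixels.csv` listing `(row, col, t1)` for every valid pixel.
#'
#' @param t1map A [T1Map-class].
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
writeT1Map <- function(t1map, dir) {
  stopifnot(is(t1map, "T1Map"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pix <- t1map@fov / dim(t1map@t1)
  t1 <- t1map@t1; t1[is.na(t1)] <- 0
  p1 <- file.path(dir, "t1.nii.gz")
  p2 <- file.path(dir, "mask.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(t1, pixdim = pix), p1)
  RNifti::writeNifti(RNifti::asNifti(t1map@mask * 1, pixdim = pix), p2)
  idx <- which(t1map@mask, arr.ind = TRUE)
  p3 <- file.path(dir, "t1_pixels.csv")
  utils::write.csv(data.frame(row = idx[, 1], col = idx[, 2],
                              t1 = t1map@t1[t1map@mask]),
                   p3, row.names = FALSE)
  invisible(c(p1, p2, p3))
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file and merges it over the built-in defaults (see
#' [defaultRunConfig()]); unknown top-level keys are an error.
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  base <- defaultRunConfig()
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  mergeList <- function(a, b) {
    for (k in names(b))
      a[[k]] <- if (is.list(a[[k]]) && is.list(b[[k]]))
        mergeList(a[[k]], b[[k]]) else b[[k]]
    a
  }
  mergeList(base, user)
}
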