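# Baseline-image lesion quantification, histology tissue fraction, and SNR
# quality control.

#' Lesion volume by intensity-histogram analysis
#'
#' Volume of lung pixels whose baseline (pre-contrast, high-quality
#' reconstruction) intensity exceeds a cutoff derived from the lung
#' intensity distribution. The default rule, mean + k * SD with k = 2, is a
#' configurable surrogate for the previously published histogram
#' delineation this package does not restate.
#'
#' @param baseline image array (slice, row, col), e.g. from
#'   \code{\link{baseline_high_quality}}.
#' @param roi a \code{lung_roi} on the same grid.
#' @param k cutoff multiplier (default 2).
#' @return list with \code{volume_ml}, \code{cutoff}, \code{n_pixels}.
#' @export
lesion_volume_histogram <- function(baseline, roi, k = 2) {
  stopifnot(inherits(roi, "lung_roi"))
  if (!all(dim(baseline) == dim(roi$mask)))
    stop("baseline image and ROI grids differ")
  vals <- baseline[roi$mask]
  if (sd(vals) == 0) stop("degenerate (constant) lung intensity distribution")
  cutoff <- mean(vals) + k * sd(vals)
  n <- sum(vals > cutoff)
  list(volume_ml = n * roi$pixel_spacing^2 * roi$slice_thickness / 1000,
       cutoff = cutoff, n_pixels = n)
}

#' Histology tissue fraction
#'
#' Fraction of region-of-interest pixels classified as tissue: intensity
#' strictly above the air threshold (pixels exactly at the threshold count
#' as air). The default threshold 900 is on the scanner-export intensity
#' scale.
#'
#' @param image single-channel intensity matrix. Multi-channel arrays
#'   (row, col, channel) are collapsed by summing channels, since the
#'   threshold exceeds the 8-bit single-channel range.
#' @param roi logical matrix of the analysed region; default whole image.
#' @param air_threshold intensity separating air from tissue (default 900).
#' @return tissue fraction in [0, 1].
#' @export
tissue_fraction <- function(image, roi = NULL, air_threshold = 900) {
  if (length(dim(image)) == 3) image <- apply(image, c(1, 2), sum)
  if (is.null(roi)) roi <- matrix(TRUE, nrow(image), ncol(image))
  if (!any(roi)) stop("empty region of interest")
  mean(image[roi] > air_threshold)
}

#' Image signal-to-noise ratio
#'
#' \code{SNR = mean(signal ROI) / sd(noise ROI)}. For magnitude images the
#' background noise is Rayleigh distributed and its SD underestimates the
#' underlying Gaussian noise; with \code{rayleigh_correction} (default) the
#' measured SD is divided by \code{sqrt(2 - pi/2)} (about 0.655) before the
#' ratio is formed.
#'
#' @param image intensity array.
#' @param signal_roi,noise_roi logical arrays; must be disjoint, the noise
#'   region outside the object.
#' @param rayleigh_correction logical, default TRUE.
#' @return SNR (dimensionless).
#' @export
snr_estimate <- function(image, signal_roi, noise_roi,
                         rayleigh_correction = TRUE) {
  if (any(signal_roi & noise_roi)) stop("signal and noise ROIs overlap")
  if (sum(noise_roi) < 2) stop("noise ROI needs at least two pixels")
  s <- mean(image[signal_roi])
  nsd <- sd(image[noise_roi])
  if (nsd == 0) stop("zero noise standard deviation")
  if (rayleigh_correction) nsd <- nsd / sqrt(2 - pi / 2)
  s / nsd
}

#' Read a histology section image
#'
#' Reads a PNG or TIFF section export, collapses multi-channel images by
#' summing channels, and applies an intensity scale to map the stored
#' values onto the scanner-export scale the air threshold (900) was
#' determined on.
#'
#' @param path image file (".png", ".tif"/".tiff").
#' @param scale multiplicative factor applied after the channel sum; e.g.
#'   a PNG stored in [0, 1] that encodes a 0-2000 scanner scale needs
#'   \code{scale = 2000}.
#' @return single-channel intensity matrix.
#' @export
read_histology <- function(path, scale = 1) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported histology format: ", ext))
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), sum)
  img * scale
}
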