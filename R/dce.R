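# Model-free DCE analysis: relative enhancement, background-drift
# correction, seven-class enhancement binning, bin and lung volumes.

#' Lung region of interest
#'
#' Binary lung mask (conventionally including vessels and high-signal areas,
#' excluding the heart) with the voxel geometry needed for volume
#' quantification.
#'
#' @param mask logical array (slice, row, col).
#' @param pixel_spacing in-plane pixel size, mm (of the grid the mask was
#'   drawn on, i.e. the reconstructed/zero-filled grid).
#' @param slice_thickness mm.
#' @return object of class \code{lung_roi}.
#' @export
lung_roi <- function(mask, pixel_spacing, slice_thickness) {
  if (!is.logical(mask) || length(dim(mask)) != 3)
    stop("'mask' must be a logical (slice, row, col) array")
  if (!any(mask)) stop("empty lung mask")
  structure(list(mask = mask, pixel_spacing = pixel_spacing,
                 slice_thickness = slice_thickness), class = "lung_roi")
}

#' Lung volume from a mask
#'
#' Voxel count times voxel volume: \code{count * pixel_spacing^2 *
#' slice_thickness / 1000} ml.
#'
#' @param roi a \code{lung_roi}.
#' @return volume in ml.
#' @export
lung_volume <- function(roi) {
  stopifnot(inherits(roi, "lung_roi"))
  sum(roi$mask) * roi$pixel_spacing^2 * roi$slice_thickness / 1000
}

#' Baseline signal map
#'
#' Per-pixel mean over the pre-injection frames (protocol: frames 1 to 50).
#' If the series records an injection time, the requested frames must end
#' before it.
#'
#' @param series an \code{image_series}.
#' @param frame_range inclusive 1-based frame range, default \code{c(1, 50)}.
#' @param t_inj optional injection time, seconds, validated against the
#'   frame mid-times.
#' @return array (slice, row, col).
#' @export
compute_baseline <- function(series, frame_range = c(1, 50), t_inj = NULL) {
  stopifnot(inherits(series, "image_series"))
  n <- dim(series$frames)[1]
  if (frame_range[2] > n)
    stop(sprintf("series has %d frames, baseline range ends at %d",
                 n, frame_range[2]))
  fr <- frame_range[1]:frame_range[2]
  if (!is.null(t_inj) && any(series$frame_mid_time[fr] >= t_inj))
    stop("baseline frame range extends past the injection time")
  apply(series$frames[fr, , , , drop = FALSE], c(2, 3, 4), mean)
}

#' Relative enhancement
#'
#' Per-pixel, per-frame relative enhancement. Default convention is signal
#' change over baseline, \code{RE(t) = (S(t) - S0)/S0} (\code{mode =
#' "delta"}); \code{mode = "ratio"} returns \code{S(t)/S0}. Pixels with
#' nonpositive baseline are excluded (set NA); their count is reported in
#' attribute \code{n_excluded}.
#'
#' @param series an \code{image_series}.
#' @param s0 baseline map from \code{\link{compute_baseline}}.
#' @param mode "delta" (default) or "ratio".
#' @return array (frame, slice, row, col) of RE values.
#' @export
relative_enhancement <- function(series, s0, mode = c("delta", "ratio")) {
  stopifnot(inherits(series, "image_series"))
  mode <- match.arg(mode)
  bad <- s0 <= 0 | !is.finite(s0)
  s0w <- s0
  s0w[bad] <- NA
  re <- sweep(series$frames, c(2, 3, 4), s0w, "/")
  if (mode == "delta") re <- re - 1
  attr(re, "n_excluded") <- sum(bad)
  attr(re, "mode") <- mode
  re
}

#' Corner background region set
#'
#' Four square regions at the image corners, the conventional place to track
#' the background signal outside the animal. Corners intersecting an object
#' mask are dropped.
#'
#' @param dim_img c(slice, row, col) of the image grid.
#' @param size square side in pixels (default 8).
#' @param exclude optional logical array of object support; overlapping
#'   corners are removed.
#' @return logical array (slice, row, col).
#' @export
corner_rois <- function(dim_img, size = 8, exclude = NULL) {
  m <- array(FALSE, dim_img)
  nr <- dim_img[2]; nc <- dim_img[3]
  corners <- list(list(1:size, 1:size),
                  list(1:size, (nc - size + 1):nc),
                  list((nr - size + 1):nr, 1:size),
                  list((nr - size + 1):nr, (nc - size + 1):nc))
  for (co in corners) {
    block <- array(FALSE, dim_img)
    block[, co[[1]], co[[2]]] <- TRUE
    if (!is.null(exclude) && any(block & exclude)) next
    m <- m | block
  }
  if (!any(m)) stop("all corner regions intersect the object support")
  m
}

#' Background drift trace
#'
#' Normalized change of the mean background signal measured outside the
#' object: \code{b(t) = (B(t) - B0)/B0} with B(t) the mean over the corner
#' regions and B0 its mean over the baseline frames. Subtracting this trace
#' from the enhancement curves removes slowly varying receiver/artefact
#' drift.
#'
#' @param series an \code{image_series}.
#' @param rois logical array of background pixels; default four 8x8 corners.
#' @param baseline_range 1-based frame range used for B0.
#' @param lung optional \code{lung_roi}; an error is raised if the
#'   background regions touch it.
#' @return numeric vector, one value per frame.
#' @export
background_trace <- function(series, rois = NULL, baseline_range = c(1, 50),
                             lung = NULL) {
  stopifnot(inherits(series, "image_series"))
  d <- dim(series$frames)[2:4]
  if (is.null(rois))
    rois <- corner_rois(d, exclude = if (is.null(lung)) NULL else lung$mask)
  if (!is.null(lung) && any(rois & lung$mask))
    stop("background regions overlap the lung mask")
  n <- dim(series$frames)[1]
  b_t <- vapply(seq_len(n), function(f) mean(series$frames[f, , , ][rois]), 0)
  b0 <- mean(b_t[baseline_range[1]:baseline_range[2]])
  if (b0 <= 0) stop("nonpositive baseline background level")
  (b_t - b0) / b0
}

#' Subtract the background drift from enhancement curves
#'
#' \code{RE_corr(t) = RE(t) - b(t)}, applied per animal before any group
#' averaging or binning.
#'
#' @param re RE array (frame, slice, row, col) or a per-frame curve.
#' @param b background trace, one value per frame.
#' @return corrected object of the same shape.
#' @export
correct_background <- function(re, b) {
  if (is.null(dim(re))) {
    if (length(re) != length(b)) stop("frame axes differ")
    return(re - b)
  }
  if (dim(re)[1] != length(b)) stop("frame axes differ")
  re - array(b, dim(re))   # frame index is fastest
}

#' Enhancement binning
#'
#' Classifies each pixel by the maximum of its (background-corrected)
#' relative enhancement over the early post-injection window against the
#' interval edges (default 1, 2, 3, 4, 8, 12), yielding seven classes 0-6:
#' class 0 below the first edge, class 6 at or above the last.
#'
#' @param re_corr corrected RE array (frame, slice, row, col).
#' @param frame_times frame mid-times, seconds.
#' @param window post-injection window \code{c(tmin, tmax)}, seconds.
#' @param thresholds increasing bin edges.
#' @return integer array (slice, row, col) of classes 0-6 (NA where RE is
#'   NA); attribute \code{peak_re} holds the per-pixel window maximum.
#' @export
bin_pixels <- function(re_corr, frame_times, window,
                       thresholds = c(1, 2, 3, 4, 8, 12)) {
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("'thresholds' must be strictly increasing")
  sel <- which(frame_times >= window[1] & frame_times <= window[2])
  if (length(sel) == 0) stop("empty post-injection window")
  peak <- apply(re_corr[sel, , , , drop = FALSE], c(2, 3, 4), max)
  cls <- array(findInterval(peak, thresholds), dim(peak))
  cls[!is.finite(peak)] <- NA_integer_
  attr(cls, "peak_re") <- peak
  cls
}

#' Bin volumes and the low-enhancement aggregate
#'
#' Volume (ml) represented by each of the seven enhancement classes within
#' the lung, plus the aggregate volume of all classes whose upper edge is at
#' or below \code{low_threshold} (default 3, i.e. classes 0-2) and its
#' fraction of the lung volume.
#'
#' @param bin_map class array from \code{\link{bin_pixels}}.
#' @param roi a \code{lung_roi} on the same grid.
#' @param thresholds the bin edges used to build the map.
#' @param low_threshold RE value separating "low enhancement" (default 3).
#' @return list with \code{volumes_ml} (named, classes 0-6),
#'   \code{lung_volume_ml}, \code{low_volume_ml}, \code{low_fraction}.
#' @export
bin_volumes <- function(bin_map, roi, thresholds = c(1, 2, 3, 4, 8, 12),
                        low_threshold = 3) {
  stopifnot(inherits(roi, "lung_roi"))
  if (!all(dim(bin_map) == dim(roi$mask)))
    stop("bin map and ROI grids differ")
  voxel_ml <- roi$pixel_spacing^2 * roi$slice_thickness / 1000
  cls <- bin_map[roi$mask]
  counts <- vapply(0:length(thresholds), function(k)
    sum(cls == k, na.rm = TRUE), 0L)
  names(counts) <- paste0("bin", 0:length(thresholds))
  low_classes <- which(thresholds <= low_threshold)   # classes 0..max-1
  low <- sum(counts[seq_len(max(low_classes))])       # classes 0,1,2 for 3
  vols <- counts * voxel_ml
  lungv <- lung_volume(roi)
  list(volumes_ml = vols, lung_volume_ml = lungv,
       low_volume_ml = unname(low * voxel_ml),
       low_fraction = unname(low * voxel_ml / lungv))
}

#' Mean lung enhancement curve
#'
#' Arithmetic mean of the (corrected) RE over the lung pixels, per frame.
#'
#' @param re RE array (frame, slice, row, col).
#' @param roi a \code{lung_roi}.
#' @return numeric vector, one value per frame.
#' @export
mean_lung_curve <- function(re, roi) {
  stopifnot(inherits(roi, "lung_roi"))
  n <- dim(re)[1]
  vapply(seq_len(n), function(f) mean(re[f, , , ][roi$mask], na.rm = TRUE), 0)
}

#' Group-average curves
#'
#' Mean and standard error of the mean across animals, per frame.
#'
#' @param curves list of per-animal curves (equal length).
#' @return list with \code{mean} and \code{sem} vectors and \code{n}.
#' @export
group_average <- function(curves) {
  if (length(curves) < 1) stop("at least one curve required")
  len <- vapply(curves, length, 0L)
  if (length(unique(len)) != 1) stop("frame counts differ across animals")
  mat <- do.call(rbind, curves)
  n <- nrow(mat)
  list(mean = colMeans(mat),
       sem = if (n > 1) apply(mat, 2, sd) / sqrt(n) else rep(0, ncol(mat)),
       n = n)
}
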