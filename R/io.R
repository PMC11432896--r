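# Standard-format readers/writers and configuration handling.

#' Write / read a 4D image series as NIfTI-1
#'
#' The series array (frame, slice, row, col) is stored with NIfTI axis
#' order (row, col, slice, frame); pixel spacing, slice thickness and the
#' frame spacing are recorded in pixdim. Frame mid-times are written to a
#' JSON sidecar next to the volume.
#'
#' @param series an \code{image_series}.
#' @param path output file (".nii" or ".nii.gz").
#' @return \code{read_image_series} returns an \code{image_series}.
#' @export
write_image_series <- function(series, path) {
  stopifnot(inherits(series, "image_series"))
  d <- dim(series$frames)
  arr <- aperm(series$frames, c(3, 4, 2, 1))
  dt <- if (d[1] > 1) diff(series$frame_mid_time[1:2]) else 1
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(series$pixel_spacing, series$pixel_spacing,
                           series$slice_thickness, dt)
  RNifti::writeNifti(img, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(frame_mid_time = series$frame_mid_time,
                            recon_meta = series$recon_meta),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image_series
#' @export
read_image_series <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  arr <- aperm(as.array(img), c(4, 3, 1, 2))
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE)
          else list(frame_mid_time = (seq_len(dim(arr)[1]) - 1) * pd[4],
                    recon_meta = list())
  structure(list(frames = arr, pixel_spacing = pd[1],
                 slice_thickness = pd[3],
                 frame_mid_time = meta$frame_mid_time,
                 recon_meta = meta$recon_meta), class = "image_series")
}

#' Write / read a single volume as NIfTI-1
#'
#' @param vol array (slice, row, col).
#' @param pixel_spacing,slice_thickness mm.
#' @param path output file.
#' @export
write_volume <- function(vol, path, pixel_spacing, slice_thickness) {
  arr <- aperm(vol, c(2, 3, 1))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(pixel_spacing, pixel_spacing, slice_thickness)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aperm(as.array(img), c(3, 1, 2))
}

#' Serialize a k-space series
#'
#' Stores the complex data and trajectory in an RDS archive with a JSON
#' sidecar describing the acquisition metadata.
#'
#' @param k a \code{kspace_series}.
#' @param path file path (".rds").
#' @export
write_kspace <- function(k, path) {
  stopifnot(inherits(k, "kspace_series"))
  saveRDS(k, path)
  jsonlite::write_json(k$meta, sub("\\.rds$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_kspace
#' @export
read_kspace <- function(path) {
  k <- readRDS(path)
  stopifnot(inherits(k, "kspace_series"))
  k
}

#' Write per-animal enhancement curves as CSV
#'
#' Columns: frame, time_s, mean_re, background.
#'
#' @param time frame mid-times, seconds.
#' @param mean_re mean lung RE per frame.
#' @param background background drift per frame.
#' @param path CSV path.
#' @export
write_curves <- function(time, mean_re, background, path) {
  write.csv(data.frame(frame = seq_along(time), time_s = time,
                       mean_re = mean_re, background = background),
            path, row.names = FALSE)
  invisible(path)
}

# deterministic polynomial rolling hash of a string (config fingerprint;
# no cryptographic intent, no external dependencies)
text_hash <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

.config_keys <- c("preset", "seed", "matrix_size", "n_slices", "n_profiles",
                  "time_scale", "noise_rel", "modulation_amp",
                  "modulation_period", "tiny_golden_order", "window", "step",
                  "mode", "zero_fill", "l1_weight", "l2_weight", "n_iter",
                  "baseline_frames", "thresholds", "low_threshold",
                  "post_window_s", "re_mode", "dc_floor", "lesion_k",
                  "baseline_spokes", "calibrate_volumes")

#' Pipeline configuration
#'
#' Builds, validates, reads and writes the configuration that drives
#' \code{\link{run_pipeline}}. Defaults equal the acquisition/analysis
#' protocol values (window 90, step 60, l1 0.00536, l2 0.0016, zero-fill 2,
#' thresholds 1,2,3,4,8,12, baseline frames 1-50). Unknown keys are
#' rejected.
#'
#' @param ... overrides of the default keys.
#' @return named list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    preset = "control", seed = 1, matrix_size = 96, n_slices = 38,
    n_profiles = NULL, time_scale = 1, noise_rel = 5e-4,
    modulation_amp = 0, modulation_period = 300, tiny_golden_order = 7,
    window = 90, step = 60, mode = "gridding", zero_fill = 2,
    l1_weight = 0.00536, l2_weight = 0.0016, n_iter = 50,
    baseline_frames = c(1, 50), thresholds = c(1, 2, 3, 4, 8, 12),
    low_threshold = 3, post_window_s = 60, re_mode = "delta",
    dc_floor = "area", lesion_k = 2, baseline_spokes = 3000,
    calibrate_volumes = FALSE)
  over <- list(...)
  unknown <- setdiff(names(over), .config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  structure(modifyList(defaults, over, keep.null = TRUE),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a \code{pipeline_config}.
#' @param path YAML file.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname pipeline_config
#' @export
config_hash <- function(config) {
  text_hash(yaml::as.yaml(unclass(config)))
}
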