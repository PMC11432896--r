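#' Tiny-golden-angle increment
#'
#' Angular increment of the generalised (tiny) golden-angle family,
#' \eqn{\psi_N = 180 / (\phi + N - 1)} degrees with \eqn{\phi = (1+\sqrt5)/2}
#' the golden ratio. Order 1 is the classical golden angle (111.246 degrees);
#' order 7 gives the 23.63 degree increment commonly used for multi-slice
#' radial lung imaging, where small per-step gradient jumps reduce eddy
#' current artefacts while any consecutive subset of spokes still covers
#' angle space quasi-uniformly.
#'
#' @param order positive integer order \eqn{N} of the tiny-golden-angle series.
#' @return increment in degrees.
#' @examples
#' tiny_golden_angle(7) # 23.63 degrees
#' @export
tiny_golden_angle <- function(order) {
  if (length(order) != 1L || !is.numeric(order) || is.na(order) ||
      order < 1 || order != round(order))
    stop("'order' must be a positive integer")
  phi <- (1 + sqrt(5)) / 2
  180 / (phi + order - 1)
}

#' Build a center-out radial trajectory
#'
#' Generates spoke angles and normalized k-space sample coordinates for a
#' center-out (half-spoke) radial UTE acquisition. Angle of profile i
#' (1-based) is \code{(i-1) * angle_increment mod 360}; sample j of a spoke
#' lies at radius \code{(j-1)/(n_samples-1) * 0.5} along the spoke direction,
#' so coordinates are normalized to \code{[-0.5, 0.5]} cycles per acquisition
#' pixel. Ramp density-compensation weights (proportional to |k|, outermost
#' sample = 1, DC sample floored) are attached.
#'
#' @param n_profiles number of radial profiles (spokes).
#' @param n_samples samples per spoke (>= 2), acquired center-out.
#' @param matrix_size acquisition matrix (used by the scaled view and
#'   reconstruction), default 96.
#' @param angle_increment angular gap between consecutive profiles, degrees;
#'   defaults to \code{tiny_golden_angle(7)}.
#' @param dc_floor weight assigned to the k = 0 sample, in (0, 0.1].
#' @return an object of class \code{radial_trajectory}: list with
#'   \code{n_profiles}, \code{n_samples}, \code{matrix_size}, \code{angles}
#'   (degrees in [0, 360)), \code{kx}, \code{ky} (profile x sample matrices),
#'   \code{radius} (per-sample |k|), and \code{weights}.
#' @export
build_trajectory <- function(n_profiles, n_samples, matrix_size = 96,
                             angle_increment = tiny_golden_angle(7),
                             dc_floor = 0.01) {
  if (n_profiles < 1) stop("'n_profiles' must be >= 1")
  if (n_samples < 2) stop("'n_samples' must be >= 2 (spoke radius undefined)")
  if (matrix_size < 1) stop("'matrix_size' must be >= 1")
  # (i * increment) mod 360 in double precision: no cumulative-sum drift
  angles <- ((seq_len(n_profiles) - 1) * angle_increment) %% 360
  radius <- (seq_len(n_samples) - 1) / (n_samples - 1) * 0.5
  a_rad <- angles * pi / 180
  kx <- outer(cos(a_rad), radius)
  ky <- outer(sin(a_rad), radius)
  traj <- structure(list(
    n_profiles = as.integer(n_profiles),
    n_samples = as.integer(n_samples),
    matrix_size = as.integer(matrix_size),
    angle_increment = angle_increment,
    angles = angles, radius = radius, kx = kx, ky = ky
  ), class = "radial_trajectory")
  traj$weights <- density_weights(traj, dc_floor = dc_floor)
  traj$dc_floor <- dc_floor
  traj
}

#' Ramp density-compensation weights
#'
#' Per-sample density compensation for radial sampling: weight proportional
#' to the radial distance |k| of the sample, normalized so the outermost
#' sample has weight 1. The k = 0 sample, whose ramp weight would be 0 and
#' hence discard the DC information entirely, is assigned \code{dc_floor}.
#'
#' @param traj a \code{radial_trajectory}.
#' @param dc_floor weight for the central (k = 0) sample: a number in
#'   (0, 0.1], or \code{"area"} for the ramp-consistent polar-cell value
#'   \eqn{\Delta r / 8} (the k = 0 cell's area relative to the first
#'   annulus). Every center-out spoke carries a k = 0 sample, so a fixed
#'   floor much larger than the area value over-weights DC and biases
#'   reconstructed intensity ratios.
#' @return matrix (profile x sample) of nonnegative weights, identical across
#'   profiles.
#' @export
density_weights <- function(traj, dc_floor = 0.01) {
  stopifnot(inherits(traj, "radial_trajectory"))
  rmax <- max(traj$radius)
  if (identical(dc_floor, "area")) {
    dr <- sort(unique(traj$radius))
    dc_floor <- (dr[2] - dr[1]) / rmax / 8
  }
  if (dc_floor <= 0 || dc_floor > 0.1)
    stop("'dc_floor' must lie in (0, 0.1]")
  w <- traj$radius / rmax
  w[traj$radius == 0] <- dc_floor
  matrix(rep(w, each = traj$n_profiles), traj$n_profiles, traj$n_samples)
}

#' Scaled trajectory view
#'
#' Trajectory coordinates multiplied by the acquisition matrix size, i.e. in
#' grid-index units with the outermost sample at |k| = matrix_size / 2.
#'
#' @param traj a \code{radial_trajectory}.
#' @return list with matrices \code{kx}, \code{ky} (profile x sample).
#' @export
scale_trajectory <- function(traj) {
  stopifnot(inherits(traj, "radial_trajectory"))
  list(kx = traj$kx * traj$matrix_size, ky = traj$ky * traj$matrix_size)
}

#' @export
print.radial_trajectory <- function(x, ...) {
  cat(sprintf(
    "radial_trajectory: %d profiles x %d samples, matrix %d, increment %.4f deg\n",
    x$n_profiles, x$n_samples, x$matrix_size, x$angle_increment))
  invisible(x)
}

#' Export / import a trajectory as plain text
#'
#' Writes one row per (profile, sample) with columns profile, sample, kx, ky,
#' weight; reads it back into a \code{radial_trajectory}-compatible list.
#'
#' @param traj a \code{radial_trajectory}.
#' @param path CSV file path.
#' @return \code{read_trajectory} returns a list with \code{kx}, \code{ky},
#'   \code{weights} matrices (profile x sample).
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "radial_trajectory"))
  idx <- expand.grid(sample = seq_len(traj$n_samples),
                     profile = seq_len(traj$n_profiles))
  df <- data.frame(profile = idx$profile, sample = idx$sample,
                   kx = as.vector(t(traj$kx)), ky = as.vector(t(traj$ky)),
                   weight = as.vector(t(traj$weights)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- read.csv(path)
  np <- max(df$profile); ns <- max(df$sample)
  ord <- order(df$profile, df$sample)
  list(
    n_profiles = np, n_samples = ns,
    kx = matrix(df$kx[ord], np, ns, byrow = TRUE),
    ky = matrix(df$ky[ord], np, ns, byrow = TRUE),
    weights = matrix(df$weight[ord], np, ns, byrow = TRUE)
  )
}
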