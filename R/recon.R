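#' Radial k-space series container
#'
#' Complex radial samples indexed (profile, sample, slice) with per-profile
#' timestamps. The multi-slice UTE looping structure acquires one spoke for
#' every slice before advancing the angle, so all slices share the profile
#' angle and the effective per-slice repetition time is
#' \code{n_slices * tr_profile}.
#'
#' @param data complex array (profile, sample, slice).
#' @param traj the \code{radial_trajectory} the data were sampled on.
#' @param tr_profile repetition time per radial profile, seconds (paper
#'   protocol: 0.003).
#' @param n_slices number of interleaved slices.
#' @param te echo time, seconds.
#' @param flip excitation flip angle, degrees.
#' @param fov field of view, mm.
#' @param slice_thickness slice thickness, mm.
#' @return object of class \code{kspace_series}.
#' @export
kspace_series <- function(data, traj, tr_profile = 0.003, n_slices = dim(data)[3],
                          te = 0.000368, flip = 40, fov = 58,
                          slice_thickness = 1.208) {
  stopifnot(inherits(traj, "radial_trajectory"))
  d <- dim(data)
  if (length(d) != 3) stop("'data' must be (profile, sample, slice)")
  if (d[1] != traj$n_profiles || d[2] != traj$n_samples)
    stop("data dimensions do not match trajectory")
  tr_eff <- n_slices * tr_profile
  structure(list(
    data = data, traj = traj,
    profile_time = (seq_len(d[1]) - 1) * tr_eff,
    meta = list(tr_profile = tr_profile, tr_eff = tr_eff,
                n_slices = as.integer(n_slices), te = te, flip = flip,
                fov = fov, slice_thickness = slice_thickness)
  ), class = "kspace_series")
}

#' @export
print.kspace_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "kspace_series: %d profiles x %d samples x %d slices, TR_eff %.1f ms, %.1f s total\n",
    d[1], d[2], d[3], x$meta$tr_eff * 1000, max(x$profile_time)))
  invisible(x)
}

#' Sliding-window frame plan
#'
#' Groups consecutive radial profiles into overlapping dynamic frames:
#' frame k (1-based) covers profiles \code{(k-1)*step + 1 .. (k-1)*step +
#' window}. With the protocol values (window 90, step 60, effective TR
#' 114 ms) each frame integrates 10.26 s of data and consecutive frames are
#' 6.84 s apart. Trailing profiles that cannot fill a window are dropped.
#'
#' @param n_profiles total profiles available.
#' @param window profiles per frame (default 90).
#' @param step profiles between consecutive frame starts (default 60).
#' @param tr_eff effective per-slice repetition time, seconds.
#' @return object of class \code{frame_plan}: list with \code{frames} (list
#'   of 1-based profile index vectors), \code{n_frames},
#'   \code{frame_duration}, \code{frame_spacing}, \code{frame_mid_time}.
#' @export
plan_sliding_window <- function(n_profiles, window = 90, step = 60,
                                tr_eff = 0.114) {
  if (step < 1 || window < step) stop("'window' >= 'step' >= 1 required")
  if (n_profiles < window)
    stop("empty plan: fewer profiles than one window")
  n_frames <- (n_profiles - window) %/% step + 1
  starts <- (seq_len(n_frames) - 1) * step
  frames <- lapply(starts, function(s) (s + 1):(s + window))
  mid <- (starts + (starts + window - 1)) / 2 * tr_eff
  structure(list(
    n_frames = as.integer(n_frames), window = as.integer(window),
    step = as.integer(step), tr_eff = tr_eff, frames = frames,
    frame_duration = window * tr_eff, frame_spacing = step * tr_eff,
    frame_mid_time = mid
  ), class = "frame_plan")
}

#' @export
print.frame_plan <- function(x, ...) {
  cat(sprintf(
    "frame_plan: %d frames, window %d / step %d profiles (%.2f s / %.2f s)\n",
    x$n_frames, x$window, x$step, x$frame_duration, x$frame_spacing))
  invisible(x)
}

check_profiles <- function(k, profiles) {
  if (length(profiles) == 0) stop("empty profile range")
  bad <- which(apply(is.na(k$data[profiles, , , drop = FALSE]), 1, any))
  if (length(bad))
    stop(sprintf("NaN in k-space data at profile(s) %s",
                 paste(profiles[bad[seq_len(min(5, length(bad)))]],
                       collapse = ", ")))
}

#' Density-compensated gridding reconstruction
#'
#' Reconstructs one image volume from the given radial profiles: samples are
#' ramp density-weighted, spread onto an oversampled Cartesian grid with a
#' Kaiser-Bessel kernel, inverse Fourier transformed, deapodized and cropped
#' to \code{matrix_size * zero_fill}. Each slice is reconstructed
#' independently (2D multislice acquisition).
#'
#' @param k a \code{kspace_series}.
#' @param profiles 1-based profile indices to use.
#' @param zero_fill k-space zero-padding factor (default 2, i.e. 96 -> 192
#'   with apparent pixel size halved).
#' @param os,width gridding oversampling and kernel width.
#' @param dc_floor DC-sample weight rule (see \code{\link{density_weights}}).
#' @param magnitude return magnitude (default) or complex images.
#' @return array (slice, row, col); attribute \code{pixel_spacing} mm.
#' @export
grid_reconstruct <- function(k, profiles, zero_fill = 2, os = 1.5, width = 4,
                             dc_floor = "area", magnitude = TRUE) {
  stopifnot(inherits(k, "kspace_series"))
  check_profiles(k, profiles)
  op <- nufft_operator(k$traj, profiles, zero_fill, os, width, dc_floor)
  n_sl <- dim(k$data)[3]
  out <- if (magnitude) array(0, c(n_sl, op$M, op$M))
         else array(0 + 0i, c(n_sl, op$M, op$M))
  wsum <- sum(op$weights)
  for (s in seq_len(n_sl)) {
    y <- as.vector(k$data[profiles, , s])
    x <- op$adjoint(op$weights * y) / wsum   # scale-stable across spoke counts
    out[s, , ] <- if (magnitude) Mod(x) else x
  }
  attr(out, "pixel_spacing") <- k$meta$fov / op$M
  out
}

#' Wavelet-regularized iterative reconstruction
#'
#' Solves, per slice, \deqn{\min_x \|\sqrt{W}(A x - y)\|_2^2 +
#' \lambda_1 \|\Psi x\|_1 + \lambda_2 \|x\|_2^2} with A the nonuniform
#' sampling operator of the chosen profiles, W the ramp density weights
#' (applied inside the solve by default), and \eqn{\Psi} an orthonormal
#' Daubechies-4 wavelet transform. Monotone FISTA with step size from a
#' power-iteration estimate of the operator norm; the objective is
#' non-increasing by construction.
#'
#' @param k a \code{kspace_series}.
#' @param profiles profile indices.
#' @param l1_weight l1 penalty on wavelet coefficients (protocol value
#'   0.00536).
#' @param l2_weight l2 penalty (protocol value 0.0016; ratio 3.35).
#' @param n_iter FISTA iterations (default 50).
#' @param zero_fill,os,width as in \code{\link{grid_reconstruct}}.
#' @param wavelet_levels decomposition depth of the sparsity transform.
#' @param dc_in_solve apply density weights inside the data term (default
#'   TRUE); FALSE solves the unweighted least-squares problem.
#' @param dc_floor DC-sample weight rule (see \code{\link{density_weights}}).
#' @return array (slice, row, col) of magnitudes; attribute
#'   \code{objective}: per-slice objective traces.
#' @export
regularized_reconstruct <- function(k, profiles, l1_weight = 0.00536,
                                    l2_weight = 0.0016, n_iter = 50,
                                    zero_fill = 2, os = 1.5, width = 4,
                                    wavelet_levels = 3, dc_in_solve = TRUE,
                                    dc_floor = "area") {
  stopifnot(inherits(k, "kspace_series"))
  if (l1_weight < 0 || l2_weight < 0) stop("penalty weights must be >= 0")
  if (n_iter < 1) stop("'n_iter' must be >= 1")
  check_profiles(k, profiles)
  op <- nufft_operator(k$traj, profiles, zero_fill, os, width, dc_floor)
  M <- op$M
  if (M %% 2^wavelet_levels != 0)
    stop("image side must be divisible by 2^wavelet_levels")
  sw <- if (dc_in_solve) sqrt(op$weights) else rep(1, length(op$weights))
  Af <- function(x) sw * op$forward(x)
  Ah <- function(y) op$adjoint(sw * y)
  # Lipschitz constant of the gradient: 2*(||A||^2 + l2), power iteration
  L <- with_seed(20260930, {
    v <- matrix(complex(real = rnorm(M * M), imaginary = rnorm(M * M)), M, M)
    v <- v / sqrt(sum(Mod(v)^2))
    lam <- 1
    for (i in 1:30) {
      v <- Ah(Af(v))
      lam <- sqrt(sum(Mod(v)^2))
      v <- v / lam
    }
    lam
  })
  stepsz <- 1 / (2 * (L + l2_weight))
  soft <- function(w, t) {
    a <- Mod(w)
    w * ifelse(a > 0, pmax(a - t, 0) / a, 0)
  }
  objective <- function(x, y) {
    r <- Af(x) - sw * y
    sum(Mod(r)^2) + l1_weight * sum(Mod(dwt2_cplx(x, wavelet_levels))) +
      l2_weight * sum(Mod(x)^2)
  }
  n_sl <- dim(k$data)[3]
  out <- array(0, c(n_sl, M, M))
  obj_traces <- vector("list", n_sl)
  for (s in seq_len(n_sl)) {
    y <- as.vector(k$data[profiles, , s])
    # normalize the data scale so the penalty weights act on the same
    # relative scale regardless of acquisition amplitude
    ysc <- max(Mod(y))
    if (ysc == 0) ysc <- 1
    y <- y / ysc
    x <- Ah(sw * y)                       # density-compensated warm start
    z <- x; tk <- 1
    fx <- objective(x, y)
    trace <- numeric(n_iter)
    n_bad <- 0
    for (it in seq_len(n_iter)) {
      grad <- 2 * (Ah(Af(z) - sw * y) + l2_weight * z)
      xc <- z - stepsz * grad
      if (l1_weight > 0) {
        w <- dwt2_cplx(xc, wavelet_levels)
        xc <- idwt2_cplx(soft(w, stepsz * l1_weight), wavelet_levels)
      }
      fc <- objective(xc, y)
      tk1 <- (1 + sqrt(1 + 4 * tk^2)) / 2
      if (fc <= fx) {                     # monotone FISTA step
        z <- xc + (tk - 1) / tk1 * (xc - x)
        x <- xc; fx <- fc; n_bad <- 0
      } else {
        z <- x + tk / tk1 * (xc - x)      # keep best iterate
        n_bad <- n_bad + 1
        if (n_bad > 10)
          stop("objective increases persistently: step size diagnostic failure")
      }
      tk <- tk1
      trace[it] <- fx
    }
    out[s, , ] <- Mod(x) * ysc
    obj_traces[[s]] <- trace
  }
  attr(out, "pixel_spacing") <- k$meta$fov / M
  attr(out, "objective") <- obj_traces
  out
}

#' Reconstruct a sliding-window dynamic series
#'
#' Applies the per-frame reconstruction (gridding by default, optionally the
#' regularized solver) to every frame of a plan and assembles a 4D image
#' series. Frame mid-times are the midpoints of each window's profile-time
#' range.
#'
#' @param k a \code{kspace_series}.
#' @param plan a \code{frame_plan}.
#' @param mode "gridding" or "regularized".
#' @param zero_fill zero-padding factor.
#' @param ... further arguments passed to the per-frame reconstruction.
#' @return object of class \code{image_series}: list with \code{frames}
#'   (frame, slice, row, col), \code{pixel_spacing}, \code{slice_thickness},
#'   \code{frame_mid_time}, \code{recon_meta}.
#' @export
reconstruct_series <- function(k, plan, mode = c("gridding", "regularized"),
                               zero_fill = 2, ...) {
  stopifnot(inherits(k, "kspace_series"), inherits(plan, "frame_plan"))
  mode <- match.arg(mode)
  if (max(unlist(lapply(plan$frames, max))) > dim(k$data)[1])
    stop("plan exceeds available profiles")
  rec1 <- function(pr) switch(mode,
    gridding = grid_reconstruct(k, pr, zero_fill = zero_fill, ...),
    regularized = regularized_reconstruct(k, pr, zero_fill = zero_fill, ...))
  first <- rec1(plan$frames[[1]])
  d <- dim(first)
  frames <- array(0, c(plan$n_frames, d))
  frames[1, , , ] <- first
  if (plan$n_frames > 1)
    for (f in 2:plan$n_frames) frames[f, , , ] <- rec1(plan$frames[[f]])
  mid <- vapply(plan$frames, function(pr)
    (k$profile_time[pr[1]] + k$profile_time[pr[length(pr)]]) / 2, 0)
  structure(list(
    frames = frames,
    pixel_spacing = attr(first, "pixel_spacing"),
    slice_thickness = k$meta$slice_thickness,
    frame_mid_time = mid,
    recon_meta = list(mode = mode, window = plan$window, step = plan$step,
                      zero_fill = zero_fill)
  ), class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "image_series: %d frames x %d slices x %dx%d, pixel %.3f mm, slice %.3f mm\n",
    d[1], d[2], d[3], d[4], x$pixel_spacing, x$slice_thickness))
  invisible(x)
}

#' High-quality baseline reconstruction
#'
#' Single volume from the first \code{n_spokes} (pre-injection) profiles,
#' through the same reconstruction path as the dynamic frames. Used for the
#' intensity-histogram lesion quantification, where streak artefact from a
#' 90-spoke frame would dominate.
#'
#' @param k a \code{kspace_series}.
#' @param n_spokes baseline profiles to use (protocol value 3000).
#' @param mode,zero_fill,... as in \code{\link{reconstruct_series}}.
#' @return array (slice, row, col).
#' @export
baseline_high_quality <- function(k, n_spokes = 3000,
                                  mode = c("gridding", "regularized"),
                                  zero_fill = 2, ...) {
  stopifnot(inherits(k, "kspace_series"))
  mode <- match.arg(mode)
  if (dim(k$data)[1] < n_spokes)
    stop(sprintf("only %d baseline profiles available, %d requested",
                 dim(k$data)[1], n_spokes))
  pr <- seq_len(n_spokes)
  switch(mode,
    gridding = grid_reconstruct(k, pr, zero_fill = zero_fill, ...),
    regularized = regularized_reconstruct(k, pr, zero_fill = zero_fill, ...))
}

#' Per-sample phase correction
#'
#' Multiplies each complex sample by \code{exp(1i * phase)}; magnitudes are
#' unchanged. This is the hook through which measured-trajectory / B0
#' phase-evolution tables from scanner calibration can be applied.
#'
#' @param k a \code{kspace_series}.
#' @param phase_table radians, either a (profile, sample) matrix applied to
#'   every slice or a (profile, sample, slice) array.
#' @return a new \code{kspace_series}.
#' @export
apply_phase_correction <- function(k, phase_table) {
  stopifnot(inherits(k, "kspace_series"))
  d <- dim(k$data)
  if (is.matrix(phase_table)) {
    if (!all(dim(phase_table) == d[1:2]))
      stop("phase table shape does not match (profile, sample)")
    phase_table <- array(rep(phase_table, d[3]), d)
  }
  if (!all(dim(phase_table) == d))
    stop("phase table shape does not match data")
  k$data <- k$data * exp(1i * phase_table)
  k
}
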