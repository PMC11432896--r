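#' Compartment enhancement course
#'
#' Contrast-induced relaxation-rate change over time: zero before arrival,
#' then an uptake-times-washout product,
#' \deqn{\Delta R_1(t) = A (1 - e^{-(t-t_0)/\tau_{in}}) e^{-(t-t_0)/\tau_{out}}}
#' for \eqn{t \ge t_0}. Two interpretable time constants (uptake, washout)
#' stand in for the arterial-input/exchange physiology the phantom does not
#' model.
#'
#' @param t time, seconds (vectorized).
#' @param amplitude A, 1/s.
#' @param t0 contrast arrival time, seconds.
#' @param tau_in uptake time constant, seconds (> 0).
#' @param tau_out washout time constant, seconds (> 0).
#' @return delta-R1 at \code{t}, 1/s.
#' @export
enhancement_course <- function(t, amplitude, t0, tau_in, tau_out) {
  stopifnot(tau_in > 0, tau_out > 0)
  dt <- t - t0
  ifelse(dt < 0, 0,
         amplitude * (1 - exp(-dt / tau_in)) * exp(-dt / tau_out))
}

#' @rdname enhancement_course
#' @details \code{course_peak_time} gives the closed-form maximiser
#'   \eqn{\tau_{in} \log(1 + \tau_{out}/\tau_{in})} (relative to \code{t0});
#'   \code{course_peak_factor} the course value there for A = 1.
#' @export
course_peak_time <- function(tau_in, tau_out) {
  tau_in * log(1 + tau_out / tau_in)
}

#' @rdname enhancement_course
#' @export
course_peak_factor <- function(tau_in, tau_out) {
  tp <- course_peak_time(tau_in, tau_out)
  (1 - exp(-tp / tau_in)) * exp(-tp / tau_out)
}

#' Spoiled gradient-echo steady-state signal
#'
#' \deqn{S = PD \sin\alpha (1 - E_1) / (1 - \cos\alpha E_1)}, with
#' \eqn{E_1 = \exp(-TR_{eff} (1/T_1 + \Delta R_1))}. T2*/TE decay is not
#' modelled (single fixed ultra-short echo).
#'
#' @param pd proton density, arbitrary units.
#' @param t1 baseline T1, ms (> 0).
#' @param dr1 contrast-induced relaxation-rate change, 1/s (vectorized).
#' @param flip flip angle, degrees, in (0, 90).
#' @param tr_eff effective repetition time, ms.
#' @return signal, arbitrary units.
#' @export
spgr_signal <- function(pd, t1, dr1, flip = 40, tr_eff = 114) {
  stopifnot(t1 > 0, flip > 0, flip < 90)
  a <- flip * pi / 180
  e1 <- exp(-tr_eff * (1 / t1 + dr1 / 1000))
  pd * sin(a) * (1 - e1) / (1 - cos(a) * e1)
}

#' Invert the SPGR equation for a target peak enhancement
#'
#' Finds the delta-R1 whose SPGR signal exceeds baseline by the requested
#' relative enhancement. The attainable RE is bounded above by
#' \eqn{(1 - \cos\alpha E_{1,0}) / (1 - E_{1,0}) - 1} (the T1-to-zero
#' limit); targets beyond 98 percent of that ceiling are capped with a
#' warning — at short effective TR the SPGR response saturates and very high
#' observed enhancements reflect inflow or partial-volume effects outside
#' this signal model.
#'
#' @param target_re target peak relative enhancement (delta-S over S0).
#' @param t1 baseline T1, ms.
#' @param flip flip angle, degrees.
#' @param tr_eff effective repetition time, ms.
#' @return delta-R1 in 1/s.
#' @export
delta_r1_for_peak_re <- function(target_re, t1, flip = 40, tr_eff = 114) {
  s0 <- spgr_signal(1, t1, 0, flip, tr_eff)
  a <- flip * pi / 180
  e10 <- exp(-tr_eff / t1)
  re_max <- (1 - cos(a) * e10) / (1 - e10) - 1
  re <- target_re
  if (re >= 0.98 * re_max) {
    warning(sprintf(
      "target RE %.2f exceeds the SPGR ceiling %.2f at TR_eff %.0f ms; capping",
      target_re, re_max, tr_eff))
    re <- 0.98 * re_max
  }
  uniroot(function(dr1) spgr_signal(1, t1, dr1, flip, tr_eff) / s0 - 1 - re,
          c(0, 5000), tol = 1e-10)$root
}

# K matrix (n_prof*n_samp x 2) in flattened column-major (profile fastest)
# order matching as.vector(kx)
traj_kmatrix <- function(traj) cbind(as.vector(traj$kx), as.vector(traj$ky))

#' Simulate radial k-space of a dynamic phantom
#'
#' Exact forward model: for every profile (one spoke at one time point) the
#' phantom's compartment signals are evaluated at the profile time with the
#' SPGR model and the k-space samples along the spoke are computed by direct
#' nonuniform-DFT summation over the compartment pixels (no gridding
#' approximation). Because compartments are piecewise constant, the
#' per-compartment structure factors are precomputed once per slice and the
#' time dependence enters only as a per-profile amplitude. Circularly
#' symmetric complex Gaussian noise and, optionally, a slowly varying
#' multiplicative receiver modulation (emulating non-constant artefact and
#' noise levels over the 28-minute scan) are then applied. All randomness
#' flows through a private generator seeded by \code{spec$seed}.
#'
#' @param spec a \code{phantom_spec}.
#' @param n_profiles number of radial profiles to simulate; defaults to
#'   \code{duration / tr_eff}.
#' @param traj optional \code{radial_trajectory}; defaults to a
#'   tiny-golden-angle (order 7) trajectory with \code{matrix_size} samples
#'   per spoke.
#' @return list with \code{kspace} (a \code{kspace_series}) and
#'   \code{truth} (a \code{phantom_truth}).
#' @export
simulate_kspace <- function(spec, n_profiles = NULL, traj = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(n_profiles))
    n_profiles <- floor(spec$duration / spec$tr_eff)
  if (is.null(traj))
    traj <- build_trajectory(n_profiles, spec$matrix_size, spec$matrix_size)
  stopifnot(traj$n_profiles == n_profiles)
  truth <- render_phantom(spec)
  m <- spec$matrix_size
  t_prof <- (seq_len(n_profiles) - 1) * spec$tr_eff
  enhancing <- any(!vapply(spec$entries, function(e) is.null(e$peak_re), TRUE))
  if (enhancing && max(t_prof) < spec$t_inj)
    warning("duration ends before contrast arrival: no enhancement observable")
  K <- traj_kmatrix(traj)
  # per-entry signal amplitude over profile times
  amps <- lapply(spec$entries, function(e) {
    dr1 <- if (is.null(e$peak_re)) rep(0, n_profiles)
           else enhancement_course(t_prof, e$amplitude, spec$t_inj,
                                   e$tau_in, e$tau_out)
    spgr_signal(e$pd, e$t1, dr1, spec$flip, spec$tr_eff * 1000)
  })
  data <- array(0 + 0i, c(n_profiles, traj$n_samples, spec$n_slices))
  for (s in seq_len(spec$n_slices)) {
    acc <- matrix(0 + 0i, n_profiles, traj$n_samples)
    for (i in seq_along(spec$entries)) {
      idx <- which(truth$entry_map[s, , ] == i, arr.ind = TRUE)
      if (nrow(idx) == 0) next
      P <- cbind(idx[, 1] - 1 - m / 2, idx[, 2] - 1 - m / 2)
      sf <- matrix(nudft_structure(K, P), n_profiles, traj$n_samples)
      acc <- acc + amps[[i]] * sf    # amplitude recycles down profiles
    }
    data[, , s] <- acc
  }
  noise_sd <- spec$noise_sd
  if (is.null(noise_sd)) {
    # scale to the baseline DC amplitude of the central slice
    mid <- ceiling(spec$n_slices / 2)
    dc0 <- sum(vapply(seq_along(spec$entries), function(i)
      sum(truth$entry_map[mid, , ] == i) * amps[[i]][1], 0))
    noise_sd <- spec$noise_rel * abs(dc0)
  }
  if (noise_sd > 0) {
    n <- length(data)
    data <- data + with_seed(spec$seed, {
      array(complex(real = rnorm(n, sd = noise_sd),
                    imaginary = rnorm(n, sd = noise_sd)), dim(data))
    })
  }
  k <- kspace_series(data, traj, tr_profile = spec$tr_profile,
                     n_slices = spec$n_slices, te = spec$te,
                     flip = spec$flip, fov = spec$fov,
                     slice_thickness = spec$slice_thickness)
  if (!is.null(spec$modulation))
    k <- modulate_kspace(k, modulation_trace(spec$modulation, t_prof))
  list(kspace = k, truth = truth, noise_sd = noise_sd)
}

#' Receiver modulation helpers
#'
#' \code{modulation_trace} evaluates the multiplicative modulation
#' \code{m(t) = 1 + amp * sin(2 pi t / period)}; \code{modulate_kspace}
#' multiplies every sample of profile i by \code{m[i]} (receiver-gain drift
#' affects signal and noise alike).
#'
#' @param modulation list with \code{amp} and \code{period} (seconds).
#' @param t times, seconds.
#' @export
modulation_trace <- function(modulation, t) {
  1 + modulation$amp * sin(2 * pi * t / modulation$period)
}

#' @rdname modulation_trace
#' @param k a \code{kspace_series}.
#' @param m per-profile multiplicative factors.
#' @export
modulate_kspace <- function(k, m) {
  stopifnot(inherits(k, "kspace_series"))
  if (length(m) != dim(k$data)[1])
    stop("modulation length must equal the number of profiles")
  k$data <- k$data * as.vector(m)   # profile index is fastest
  k
}

#' Synthetic histology section
#'
#' Generates an alveolar-like binary texture with a known tissue fraction: a
#' Gaussian random field is smoothed in Fourier space at the requested
#' texture scale and thresholded at the (1 - f_true) quantile, then tissue
#' and air pixels receive intensities on the scanner-export scale straddling
#' the air threshold of 900. By construction the recovered tissue fraction
#' equals \code{f_true} to within one pixel in the field plus the
#' (negligible) intensity-tail overlap.
#'
#' @param f_true true tissue fraction in (0, 1].
#' @param size image side, pixels.
#' @param texture_scale correlation length of the texture, pixels.
#' @param seed RNG seed.
#' @return list with \code{image} (intensity matrix), \code{tissue_mask},
#'   \code{f_true}, and \code{air_threshold} (900).
#' @export
synth_histology <- function(f_true, size = 256, texture_scale = 8, seed = 1) {
  if (f_true <= 0 || f_true > 1) stop("'f_true' must be in (0, 1]")
  with_seed(seed, {
    if (f_true == 1) {
      tissue <- matrix(TRUE, size, size)
    } else {
      z <- matrix(rnorm(size^2), size, size)
      fr <- c(0:(size / 2), (size / 2 - 1):1) / size   # fftfreq magnitudes
      r2 <- outer(fr^2, fr^2, "+")
      filt <- exp(-r2 * (2 * pi * texture_scale)^2 / 2)
      sm <- Re(fft(fft(z) * filt, inverse = TRUE)) / size^2
      cut <- quantile(sm, 1 - f_true)
      tissue <- sm > cut
    }
    img <- matrix(0, size, size)
    img[tissue] <- 1500 + rnorm(sum(tissue), sd = 60)
    img[!tissue] <- 420 + rnorm(sum(!tissue), sd = 60)
    img <- pmax(img, 0)
    list(image = img, tissue_mask = tissue, f_true = f_true,
         air_threshold = 900)
  })
}
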