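# Kaiser-Bessel gridding machinery: sparse interpolation operator between
# nonuniform radial samples and an oversampled Cartesian k-grid, unitary
# centered FFTs, and analytic deapodization. The forward/adjoint pair built
# here is the sampling operator A used by both the one-shot gridded
# reconstruction (x = A^H W y) and the iterative regularized solver.

# Kaiser-Bessel beta for given kernel width (grid cells) and oversampling,
# Beatty's minimal-aliasing-error prescription.
kb_beta <- function(width, os) {
  pi * sqrt((width / os)^2 * (os - 0.5)^2 - 0.8)
}

# Kernel value at offset u grid cells from a sample (|u| <= width/2).
kb_kernel <- function(u, width, beta) {
  t <- 1 - (2 * u / width)^2
  v <- ifelse(t > 0, besselI(beta * sqrt(pmax(t, 0)), 0), 0)
  ifelse(abs(u) <= width / 2, v / besselI(beta, 0), 0)
}

# Image-domain transform of the kernel (deapodization profile), evaluated at
# pixel offset n from center on a G-point oversampled field. Analytic
# continuation sinh(z)/z -> sin(|z|)/|z| where the argument turns imaginary.
kb_apodization <- function(n, G, width, beta) {
  z2 <- beta^2 - (pi * width * n / G)^2
  z <- sqrt(abs(z2))
  val <- ifelse(z2 > 0, sinh(z) / z, ifelse(z == 0, 1, sin(z) / z))
  val / (sinh(beta) / beta)
}

fftshift2 <- function(x) {
  d <- dim(x)
  x[c((d[1] / 2 + 1):d[1], 1:(d[1] / 2)), c((d[2] / 2 + 1):d[2], 1:(d[2] / 2))]
}
# even sizes only, so ifftshift == fftshift
ifftshift2 <- fftshift2

# Sparse spreading matrix S (n_samples x G^2): row s holds the kernel
# footprint of sample s on the centered oversampled grid (periodic wrap).
# kx, ky in cycles per acquisition pixel; grid coordinate = k * G / zf
# with G the oversampled grid for the zero-filled matrix.
interp_matrix <- function(kx, ky, G, zf, width, beta) {
  gx <- as.vector(kx) * G / zf
  gy <- as.vector(ky) * G / zf
  ns <- length(gx)
  ixf <- floor(gx); iyf <- floor(gy)
  half <- width / 2
  offs <- seq(-(half - 1), half)     # width integer offsets around floor
  trip_i <- trip_j <- trip_x <- vector("list", width^2)
  m <- 0
  for (dx in offs) {
    jx <- ixf + dx
    wx <- kb_kernel(gx - jx, width, beta)
    cx <- ((jx + G / 2) %% G) + 1
    for (dy in offs) {
      jy <- iyf + dy
      wy <- kb_kernel(gy - jy, width, beta)
      cy <- ((jy + G / 2) %% G) + 1
      m <- m + 1
      trip_i[[m]] <- seq_len(ns)
      trip_j[[m]] <- (cy - 1) * G + cx
      trip_x[[m]] <- wx * wy
    }
  }
  Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                       x = unlist(trip_x), dims = c(ns, G * G))
}

#' Nonuniform sampling operator for a radial profile subset
#'
#' Builds the forward/adjoint pair of the Kaiser-Bessel nonuniform Fourier
#' sampling operator A for the given profiles of a radial trajectory:
#' forward maps an M x M complex image (M = matrix_size x zero_fill) to the
#' complex samples of those profiles; adjoint is its exact conjugate
#' transpose. Unitary FFT scaling is used so the adjoint test holds to
#' machine precision.
#'
#' @param traj a \code{radial_trajectory}.
#' @param profiles integer vector of profile indices (1-based).
#' @param zero_fill k-space zero-padding factor (1 = acquisition matrix).
#' @param os grid oversampling factor (default 1.5).
#' @param width kernel width in grid cells (default 4).
#' @param dc_floor DC-sample weight rule passed to
#'   \code{\link{density_weights}}; the default \code{"area"} uses the
#'   ramp-consistent polar-cell value.
#' @return list with functions \code{forward(x)}, \code{adjoint(y)}, the
#'   density \code{weights} vector for those samples, image size \code{M},
#'   grid size \code{G}.
#' @export
nufft_operator <- function(traj, profiles, zero_fill = 2, os = 1.5, width = 4,
                           dc_floor = "area") {
  stopifnot(inherits(traj, "radial_trajectory"))
  if (length(profiles) == 0) stop("empty profile range")
  if (any(profiles < 1 | profiles > traj$n_profiles))
    stop("profile indices out of range")
  M <- traj$matrix_size * zero_fill
  G <- 2 * ceiling(os * M / 2)
  beta <- kb_beta(width, G / M)
  S <- interp_matrix(traj$kx[profiles, , drop = FALSE],
                     traj$ky[profiles, , drop = FALSE],
                     G, zero_fill, width, beta)
  St <- Matrix::t(S)
  n <- (seq_len(M) - 1) - M / 2
  apod <- outer(kb_apodization(n, G, width, beta),
                kb_apodization(n, G, width, beta))
  pad <- (G - M) / 2
  idx <- (pad + 1):(pad + M)
  # Matrix's sparse products are real-only; complex vectors go through in
  # two parts
  smul <- function(A, v)
    as.vector(A %*% Re(v)) + 1i * as.vector(A %*% Im(v))
  forward <- function(x) {
    stopifnot(all(dim(x) == c(M, M)))
    xg <- matrix(0 + 0i, G, G)
    xg[idx, idx] <- x / apod
    kc <- fftshift2(fft(ifftshift2(xg))) / G
    smul(S, as.vector(kc))
  }
  adjoint <- function(y) {
    kc <- matrix(smul(St, y), G, G)
    xg <- fftshift2(fft(ifftshift2(kc), inverse = TRUE)) / G
    xg[idx, idx] / apod
  }
  w <- as.vector(density_weights(traj, dc_floor)[profiles, , drop = FALSE])
  list(forward = forward, adjoint = adjoint, weights = w,
       M = M, G = G, width = width, beta = beta)
}
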