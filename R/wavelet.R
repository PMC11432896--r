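# Orthonormal Daubechies-4 discrete wavelet transform, periodized, used as
# the default sparsity transform Psi of the regularized reconstruction.
# Psi is orthogonal, so prox of lambda*||Psi x||_1 is Psi^T soft(Psi x).

.db4_h <- c(0.4829629131445341, 0.8365163037378079,
            0.2241438680420134, -0.1294095225512604)
.db4_g <- c(.db4_h[4], -.db4_h[3], .db4_h[2], -.db4_h[1])

dwt_step <- function(x) {
  n <- length(x)
  i0 <- 2 * (seq_len(n / 2) - 1)                 # 0-based even starts
  idx <- outer(i0, 0:3, "+") %% n + 1            # periodized taps
  xm <- matrix(x[idx], n / 2, 4)
  list(a = as.vector(xm %*% .db4_h), d = as.vector(xm %*% .db4_g))
}

idwt_step <- function(a, d) {
  n <- 2 * length(a)
  x <- numeric(n)
  i0 <- 2 * (seq_len(n / 2) - 1)
  for (t in 0:3) {
    pos <- (i0 + t) %% n + 1
    contrib <- a * .db4_h[t + 1] + d * .db4_g[t + 1]
    x[pos] <- x[pos] + contrib
  }
  x
}

#' 2D periodized Daubechies-4 wavelet transform
#'
#' Orthonormal separable 2D DWT (and inverse) with the db4 filter, periodic
#' boundary handling, recursing on the approximation block. The side length
#' must be divisible by \code{2^levels}.
#'
#' @param x real matrix (square, dyadic-compatible side).
#' @param levels decomposition depth (default 3).
#' @return matrix of the same size holding the coefficient layout
#'   (approximation block in the top-left corner).
#' @export
dwt2 <- function(x, levels = 3) {
  n <- nrow(x)
  if (n %% 2^levels != 0) stop("side must be divisible by 2^levels")
  out <- x
  for (l in seq_len(levels)) {
    m <- n / 2^(l - 1)
    blk <- out[1:m, 1:m, drop = FALSE]
    # columns then rows
    tmp <- apply(blk, 2, function(col) { s <- dwt_step(col); c(s$a, s$d) })
    tmp <- t(apply(tmp, 1, function(row) { s <- dwt_step(row); c(s$a, s$d) }))
    out[1:m, 1:m] <- tmp
  }
  out
}

#' @rdname dwt2
#' @param w coefficient matrix as produced by \code{dwt2}.
#' @export
idwt2 <- function(w, levels = 3) {
  n <- nrow(w)
  if (n %% 2^levels != 0) stop("side must be divisible by 2^levels")
  out <- w
  for (l in rev(seq_len(levels))) {
    m <- n / 2^(l - 1)
    blk <- out[1:m, 1:m, drop = FALSE]
    tmp <- t(apply(blk, 1, function(row)
      idwt_step(row[1:(m / 2)], row[(m / 2 + 1):m])))
    tmp <- apply(tmp, 2, function(col)
      idwt_step(col[1:(m / 2)], col[(m / 2 + 1):m]))
    out[1:m, 1:m] <- tmp
  }
  out
}

# complex images: transform real and imaginary parts independently
dwt2_cplx <- function(x, levels = 3)
  dwt2(Re(x), levels) + 1i * dwt2(Im(x), levels)
idwt2_cplx <- function(w, levels = 3)
  idwt2(Re(w), levels) + 1i * idwt2(Im(w), levels)
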