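# Independent oracles and shared fixtures, built in code.

# NRMSE after optimal scaling (reconstruction amplitudes are arbitrary)
nrmse_opt <- function(ref, x) {
  sc <- sum(ref * x) / sum(x^2)
  sqrt(sum((ref - sc * x)^2) / sum(ref^2))
}

# Direct (slow) nonuniform-DFT adjoint: x[r, c] = sum_s w_s y_s
# exp(+2i pi (kx_s p_r + ky_s p_c)), positions in acquisition-pixel units.
# Written independently of the package's gridding path.
oracle_nudft_adjoint <- function(kx, ky, w, y, M, zf = 1) {
  p <- ((seq_len(M) - 1) - M / 2) / zf
  A <- exp(2i * pi * outer(p, kx))         # M x n_samples (rows)
  B <- exp(2i * pi * outer(p, ky))         # M x n_samples (cols)
  wy <- w * y
  A %*% (wy * t(B))
}

# Direct forward NUDFT of a pixel set (unit values), independent of src/
oracle_nudft_forward <- function(kx, ky, pr, pc, vals = 1) {
  ph <- -2i * pi * (outer(kx, pr) + outer(ky, pc))
  as.vector(exp(ph) %*% rep(vals, length.out = length(pr)))
}

# nearest-neighbour mask upsampling to a zero-filled grid
upsample3 <- function(mask, zf) {
  d <- dim(mask)
  out <- array(FALSE, c(d[1], d[2] * zf, d[3] * zf))
  for (s in seq_len(d[1]))
    out[s, , ] <- kronecker(mask[s, , ], matrix(1, zf, zf)) > 0
  out
}
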