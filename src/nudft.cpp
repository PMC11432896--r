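// Direct-summation nonuniform DFT kernels for the phantom k-space simulator.
// Exactness is the point: these evaluate sum_p x_p exp(-2i*pi*k.u_p) without
// gridding approximation, so they can serve as the forward model against
// which the fast reconstruction path is validated.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// Structure factor of a unit-valued pixel set at arbitrary k-locations.
// K: n_k x 2 (kx, ky) in cycles per pixel; P: n_pix x 2 pixel positions.
// Chunked over k rows to bound the phase-matrix memory footprint.
// [[Rcpp::export]]
arma::cx_vec nudft_structure(const arma::mat& K, const arma::mat& P) {
    const uword nk = K.n_rows;
    cx_vec out(nk, fill::zeros);
    if (P.n_rows == 0 || nk == 0) return out;
    const uword chunk = 2048;
    const vec ones_p(P.n_rows, fill::ones);
    for (uword i0 = 0; i0 < nk; i0 += chunk) {
        uword i1 = std::min(i0 + chunk, nk) - 1;
        mat ph = K.rows(i0, i1) * P.t();
        ph *= -2.0 * datum::pi;
        out.subvec(i0, i1) = cx_vec(cos(ph) * ones_p, sin(ph) * ones_p);
    }
    return out;
}

// Weighted forward NUDFT: y_k = sum_p x_p exp(-2i*pi*k.u_p), complex x.
// [[Rcpp::export]]
arma::cx_vec nudft_forward(const arma::mat& K, const arma::mat& P,
                           const arma::cx_vec& x) {
    const uword nk = K.n_rows;
    cx_vec out(nk, fill::zeros);
    if (P.n_rows == 0 || nk == 0) return out;
    if (x.n_elem != P.n_rows) Rcpp::stop("length(x) must match nrow(P)");
    const uword chunk = 2048;
    for (uword i0 = 0; i0 < nk; i0 += chunk) {
        uword i1 = std::min(i0 + chunk, nk) - 1;
        mat ph = K.rows(i0, i1) * P.t();
        ph *= -2.0 * datum::pi;
        out.subvec(i0, i1) = cx_mat(cos(ph), sin(ph)) * x;
    }
    return out;
}

// Adjoint NUDFT: x_p = sum_k y_k exp(+2i*pi*k.u_p).
// [[Rcpp::export]]
arma::cx_vec nudft_adjoint(const arma::mat& K, const arma::mat& P,
                           const arma::cx_vec& y) {
    const uword np = P.n_rows;
    cx_vec out(np, fill::zeros);
    if (np == 0 || K.n_rows == 0) return out;
    if (y.n_elem != K.n_rows) Rcpp::stop("length(y) must match nrow(K)");
    const uword chunk = 2048;
    for (uword i0 = 0; i0 < K.n_rows; i0 += chunk) {
        uword i1 = std::min(i0 + chunk, K.n_rows) - 1;
        mat ph = P * K.rows(i0, i1).t();
        ph *= 2.0 * datum::pi;
        out += cx_mat(cos(ph), sin(ph)) * y.subvec(i0, i1);
    }
    return out;
}
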