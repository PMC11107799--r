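// Hot kernel of the slant wavenumber-frequency reconstruction: for one
// spatial window of the S-transform volume, build the slant-phase slice
// SF(z, x) = Hw(z, x, tau = xbar/u) for every steering group velocity u,
// take the zero-padded 2D spatial FFT amplitude of each, and keep the
// element-wise maximum over u. Mirrors the reference R implementation
// (slant_slice / spectral_amplitude / max_over_steering) exactly.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
arma::mat steer_max_spectrum_cpp(const arma::cx_cube& Hw,
                                 const arma::mat& taper,
                                 const arma::vec& xbar,
                                 const arma::vec& u,
                                 double dt, int pz, int px,
                                 double dz, double dx) {
  const int nz = Hw.n_rows, nx = Hw.n_cols, ntau = Hw.n_slices;
  arma::mat K(pz, px, arma::fill::zeros);
  arma::cx_mat SF(pz, px);
  const double scale = dz * dx;
  for (arma::uword iu = 0; iu < u.n_elem; ++iu) {
    SF.zeros();
    for (int ix = 0; ix < nx; ++ix) {
      const double idx = xbar(ix) / u(iu) / dt;
      const int i0 = (int)std::floor(idx);
      if (i0 < 0 || i0 >= ntau) continue;     // tau beyond record -> 0
      const double wfrac = idx - i0;
      arma::cx_vec col = Hw.slice(i0).col(ix) * (1.0 - wfrac);
      if (i0 + 1 < ntau) col += Hw.slice(i0 + 1).col(ix) * wfrac;
      SF.submat(0, ix, nz - 1, ix) = col % taper.col(ix);
    }
    arma::mat A = arma::abs(arma::fft2(SF)) * scale;
    K = arma::max(K, A);
  }
  return K;
}
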