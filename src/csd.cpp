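#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Predicted cross-spectral density of the linearized generative model:
//   G_y(f) = H(f) G_v(f) H(f)^H + G_e(f) I
//   H(f)   = diag(B_r(f)) (i 2 pi f I - A)^{-1}
// where B_r(f) is the small-signal transfer function of the balloon model
// (vasodilatory signal -> flow -> volume/deoxyhemoglobin -> BOLD),
// linearized about its resting fixed point, and G_v, G_e are power-law
// spectral densities alpha * f^-beta (clamped below fmin).
// [[Rcpp::export]]
arma::cx_cube csd_predict_cpp(const arma::vec& freq, const arma::mat& A,
                              const arma::vec& transit, const arma::vec& decay,
                              double autoreg, double stiffness, double oef,
                              double efficacy, double V0, double k1, double k2,
                              double k3, double alphaState, double betaState,
                              double alphaObs, double betaObs, double fmin) {
  const uword n = A.n_rows, nf = freq.n_elem;
  cx_cube G(n, n, nf);
  const double cf = 1.0 + (1.0 - oef) * std::log(1.0 - oef) / oef;
  const cx_mat Ac(A, zeros(n, n));
  const cx_mat In(eye(n, n), zeros(n, n));
  cx_vec B(n);
  for (uword k = 0; k < nf; ++k) {
    const double f = freq(k);
    const cx_double s(0.0, 2.0 * datum::pi * f);
    cx_mat Hn = inv(s * In - Ac);
    for (uword r = 0; r < n; ++r) {
      const cx_double Fl = efficacy / (s * s + decay(r) * s + autoreg);
      const cx_double Vl = Fl / (transit(r) * s + 1.0 / stiffness);
      const cx_double Ql = (cf * Fl - (1.0 / stiffness - 1.0) * Vl) /
                           (transit(r) * s + 1.0);
      B(r) = V0 * (-(k1 + k2) * Ql + (k2 - k3) * Vl);
    }
    Hn.each_col([&](cx_vec& col) { col %= B; });  // diag(B) * Hn
    const double fc = std::max(f, fmin);
    const double gv = alphaState * std::pow(fc, -betaState);
    const double ge = alphaObs * std::pow(fc, -betaObs);
    cx_mat Gy = gv * (Hn * Hn.t());
    Gy.diag() += ge;
    G.slice(k) = 0.5 * (Gy + Gy.t());
  }
  return G;
}
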