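// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <complex>
using namespace Rcpp;

// Transfer function of the linearised, conduction-delayed circuit.
//
// Eliminating the current states from the second-order dynamics gives,
// per angular frequency w (rad/ms),
//   M(w) xv = B,   M(w) = (iw)^2 I + 2 K iw + K^2 - K (A o S' o E(w))
// with E(w) = exp(-iwD) on between-population entries (1 on the
// diagonal), K = diag(kappa), and B = C kappa_SS e1. The observed
// response is H(w) = L' xv. The 4x4 complex system is solved by
// Gaussian elimination with partial pivoting.
// [[Rcpp::export]]
ComplexVector cmc_transfer_cpp(NumericVector kappa, NumericMatrix A,
                               double Sp, double C, NumericVector L,
                               double D, NumericVector omega) {
  typedef std::complex<double> cplx;
  int nw = omega.size();
  ComplexVector out(nw);
  double KA[4][4];
  for (int p = 0; p < 4; ++p)
    for (int q = 0; q < 4; ++q)
      KA[p][q] = kappa[p] * A(p, q) * Sp;
  for (int k = 0; k < nw; ++k) {
    double w = omega[k];
    cplx iw(0.0, w);
    cplx ph = std::exp(cplx(0.0, -w * D));
    cplx M[4][5];
    for (int p = 0; p < 4; ++p) {
      for (int q = 0; q < 4; ++q) {
        cplx m = -KA[p][q] * (p == q ? cplx(1.0, 0.0) : ph);
        if (p == q)
          m += iw * iw + 2.0 * kappa[p] * iw + kappa[p] * kappa[p];
        M[p][q] = m;
      }
      M[p][4] = (p == 0) ? cplx(C * kappa[0], 0.0) : cplx(0.0, 0.0);
    }
    // forward elimination with partial pivoting
    bool singular = false;
    for (int col = 0; col < 4 && !singular; ++col) {
      int piv = col;
      double best = std::abs(M[col][col]);
      for (int rr = col + 1; rr < 4; ++rr)
        if (std::abs(M[rr][col]) > best) { best = std::abs(M[rr][col]); piv = rr; }
      if (best == 0.0) { singular = true; break; }
      if (piv != col)
        for (int cc = col; cc < 5; ++cc) std::swap(M[col][cc], M[piv][cc]);
      for (int rr = col + 1; rr < 4; ++rr) {
        cplx f = M[rr][col] / M[col][col];
        for (int cc = col; cc < 5; ++cc) M[rr][cc] -= f * M[col][cc];
      }
    }
    cplx h(0.0, 0.0);
    if (!singular) {
      cplx xv[4];
      for (int rr = 3; rr >= 0; --rr) {
        cplx s = M[rr][4];
        for (int cc = rr + 1; cc < 4; ++cc) s -= M[rr][cc] * xv[cc];
        xv[rr] = s / M[rr][rr];
      }
      for (int p = 0; p < 4; ++p) h += L[p] * xv[p];
    } else {
      h = cplx(R_PosInf, 0.0);
    }
    out[k] = Rcomplex{h.real(), h.imag()};
  }
  return out;
}
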