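#include <Rcpp.h>
using namespace Rcpp;

// Second-order synaptic dynamics of the four-population circuit.
// State: x[0..3] membrane potentials, x[4..7] postsynaptic currents.
// Between-population coupling reads the delayed voltages vd; self-coupling
// and the leak terms use the instantaneous state.
static inline void deriv(const double *x, const double *vd, double u,
                         const double *A, const double *kappa, double r,
                         double C, double *dx) {
  double S[4], Sd[4];
  for (int p = 0; p < 4; ++p) {
    S[p] = 1.0 / (1.0 + std::exp(-r * x[p])) - 0.5;
    Sd[p] = 1.0 / (1.0 + std::exp(-r * vd[p])) - 0.5;
  }
  for (int p = 0; p < 4; ++p) {
    double U = 0.0;
    for (int q = 0; q < 4; ++q)
      U += A[p + 4 * q] * (p == q ? S[q] : Sd[q]); // column-major A[target, source]
    if (p == 0) U += C * u; // exogenous drive onto SS
    double k = kappa[p];
    dx[p] = x[4 + p];
    dx[4 + p] = k * U - 2.0 * k * x[4 + p] - k * k * x[p];
  }
}

// voltages at time (t_now - delay), linearly interpolated from the stored
// per-step history; times before the start return the initial voltages
static inline void delayed_v(const std::vector<double> &hist, int nstored,
                             double steps_back, const double *x0,
                             const double *xnow, double *vd) {
  if (steps_back <= 0.0) {
    for (int p = 0; p < 4; ++p) vd[p] = xnow[p];
    return;
  }
  double pos = nstored - steps_back; // fractional index into history
  if (pos <= 0.0) {
    for (int p = 0; p < 4; ++p) vd[p] = x0[p];
    return;
  }
  int i0 = (int)std::floor(pos);
  double w = pos - i0;
  for (int p = 0; p < 4; ++p) {
    double lo = (i0 == 0) ? x0[p] : hist[4 * (i0 - 1) + p];
    double hi = (i0 >= nstored) ? xnow[p] : hist[4 * i0 + p];
    vd[p] = lo * (1.0 - w) + hi * w;
  }
}

// Fixed-step RK4 with zero-order-hold input and delayed between-population
// coupling; returns voltages only.
// [[Rcpp::export]]
NumericMatrix cmc_rk4(NumericMatrix A, NumericVector kappa, double r,
                      double C, NumericVector input, double dt,
                      NumericVector x0, double bound, double delay_ms) {
  int n = input.size();
  NumericMatrix out(n, 4);
  double x[8], k1[8], k2[8], k3[8], k4[8], tmp[8], vd[4], xinit[4];
  for (int i = 0; i < 8; ++i) x[i] = x0[i];
  for (int p = 0; p < 4; ++p) xinit[p] = x0[p];
  const double *Ap = A.begin();
  const double *kp = kappa.begin();
  double dsteps = delay_ms / dt;
  std::vector<double> hist;
  hist.reserve(4 * n);
  double vdh[4], vd1[4];
  for (int t = 0; t < n; ++t) {
    double u = input[t];
    // delayed voltages interpolated at the RK4 substep times
    delayed_v(hist, t, dsteps, xinit, x, vd);
    delayed_v(hist, t, dsteps - 0.5, xinit, x, vdh);
    delayed_v(hist, t, dsteps - 1.0, xinit, x, vd1);
    deriv(x, vd, u, Ap, kp, r, C, k1);
    for (int i = 0; i < 8; ++i) tmp[i] = x[i] + 0.5 * dt * k1[i];
    deriv(tmp, vdh, u, Ap, kp, r, C, k2);
    for (int i = 0; i < 8; ++i) tmp[i] = x[i] + 0.5 * dt * k2[i];
    deriv(tmp, vdh, u, Ap, kp, r, C, k3);
    for (int i = 0; i < 8; ++i) tmp[i] = x[i] + dt * k3[i];
    deriv(tmp, vd1, u, Ap, kp, r, C, k4);
    for (int i = 0; i < 8; ++i)
      x[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    for (int p = 0; p < 4; ++p) {
      if (!std::isfinite(x[p]) || std::fabs(x[p]) > bound)
        stop("simulation diverged at step %d (|x_v| > bound)", t + 1);
      out(t, p) = x[p];
      hist.push_back(x[p]);
    }
  }
  return out;
}
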