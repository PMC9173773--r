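#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Two-moment description of amyloid fibril formation.
// State: P (fibril number concentration), M (fibril mass concentration),
// m (free monomer). The monomer is integrated as an explicit state rather
// than eliminated via m = mtot - M, so that mass conservation m + M = const
// is a genuine consistency check on the integrator, not an identity.
//
//   dP/dt = kn * m^nc + k2 * m^n2 * M     (primary + secondary nucleation)
//   dM/dt = 2 * kplus * m * P             (elongation at both fibril ends)
//   dm/dt = -2 * kplus * m * P

struct Rates {
  double kn, k2, kplus, nc, n2;
};

static inline void deriv(const Rates &r, double P, double M, double m,
                         double &dP, double &dM, double &dm) {
  double mc = m > 0.0 ? m : 0.0;
  dP = r.kn * std::pow(mc, r.nc) + r.k2 * std::pow(mc, r.n2) * M;
  double elong = 2.0 * r.kplus * mc * P;
  dM = elong;
  dm = -elong;
}

// [[Rcpp::export(name = ".integrate_moments")]]
NumericMatrix integrate_moments(NumericVector times, double kn, double k2,
                                double kplus, double nc, double n2,
                                double m0, double M0, double P0,
                                int n_steps) {
  int nt = times.size();
  if (nt < 1) stop("no output times");
  double t_end = times[nt - 1];
  if (t_end < 0) stop("negative time");
  if (n_steps < 1) stop("n_steps must be positive");
  double dt = t_end > 0 ? t_end / n_steps : 0.0;

  Rates r{kn, k2, kplus, nc, n2};
  NumericMatrix out(nt, 3);
  colnames(out) = CharacterVector::create("P", "M", "m");

  double P = P0, M = M0, m = m0, t = 0.0;
  int oi = 0;
  // emit any output times at/before t = 0
  while (oi < nt && times[oi] <= 0.0) {
    out(oi, 0) = P; out(oi, 1) = M; out(oi, 2) = m; ++oi;
  }
  double Pp = P, Mp = M, mp = m, tp = t;  // previous step, for interpolation
  for (int s = 0; s < n_steps && oi < nt; ++s) {
    Pp = P; Mp = M; mp = m; tp = t;
    double k1P, k1M, k1m, k2P, k2M, k2m, k3P, k3M, k3m, k4P, k4M, k4m;
    deriv(r, P, M, m, k1P, k1M, k1m);
    deriv(r, P + 0.5 * dt * k1P, M + 0.5 * dt * k1M, m + 0.5 * dt * k1m,
          k2P, k2M, k2m);
    deriv(r, P + 0.5 * dt * k2P, M + 0.5 * dt * k2M, m + 0.5 * dt * k2m,
          k3P, k3M, k3m);
    deriv(r, P + dt * k3P, M + dt * k3M, m + dt * k3m, k4P, k4M, k4m);
    P += dt / 6.0 * (k1P + 2 * k2P + 2 * k3P + k4P);
    M += dt / 6.0 * (k1M + 2 * k2M + 2 * k3M + k4M);
    m += dt / 6.0 * (k1m + 2 * k2m + 2 * k3m + k4m);
    if (m < 0.0) { M += m; m = 0.0; }  // clamp tiny overshoot, keep m+M exact
    t = (s + 1) * dt;
    while (oi < nt && times[oi] <= t + 1e-12 * (t_end > 0 ? t_end : 1.0)) {
      double w = (dt > 0) ? (times[oi] - tp) / dt : 0.0;
      out(oi, 0) = Pp + w * (P - Pp);
      out(oi, 1) = Mp + w * (M - Mp);
      out(oi, 2) = mp + w * (m - mp);
      ++oi;
    }
  }
  while (oi < nt) {  // numerical tail (times at t_end)
    out(oi, 0) = P; out(oi, 1) = M; out(oi, 2) = m; ++oi;
  }
  return out;
}
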