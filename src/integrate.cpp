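#include <Rcpp.h>
using namespace Rcpp;

// Two-population Wilson-Cowan vector field with sigmoidal response.
// Parameter vector layout: w_EE, w_IE, w_EI, beta, threshold, tau_E, tau_I.
// Drive vector layout: kind (0 constant, 1 sinusoid), mean, amplitude,
// frequency (Hz), phase offset (radians).

static inline double sigm(double x, double beta, double thr) {
  return 1.0 / (1.0 + std::exp(-beta * (x - thr)));
}

static inline double drive_at(const double* d, double t) {
  if (d[0] == 0.0) return d[1];
  return d[1] + d[2] * std::cos(2.0 * M_PI * d[3] * t + d[4]);
}

static inline void deriv(double E, double I, double thE, double thI,
                         const double* p, double& dE, double& dI) {
  // p: wEE, wIE, wEI, beta, thr, tauE, tauI
  dE = (-E + sigm(p[0] * E - p[1] * I + thE, p[3], p[4])) / p[5];
  dI = (-I + sigm(p[2] * E + thI, p[3], p[4])) / p[6];
}

static inline void rk4_step(double& E, double& I, double t, double dt,
                            const double* p, const double* dE_spec,
                            const double* dI_spec) {
  double thE0 = drive_at(dE_spec, t), thI0 = drive_at(dI_spec, t);
  double thEh = drive_at(dE_spec, t + 0.5 * dt),
         thIh = drive_at(dI_spec, t + 0.5 * dt);
  double thE1 = drive_at(dE_spec, t + dt), thI1 = drive_at(dI_spec, t + dt);
  double k1E, k1I, k2E, k2I, k3E, k3I, k4E, k4I;
  deriv(E, I, thE0, thI0, p, k1E, k1I);
  deriv(E + 0.5 * dt * k1E, I + 0.5 * dt * k1I, thEh, thIh, p, k2E, k2I);
  deriv(E + 0.5 * dt * k2E, I + 0.5 * dt * k2I, thEh, thIh, p, k3E, k3I);
  deriv(E + dt * k3E, I + dt * k3I, thE1, thI1, p, k4E, k4I);
  E += dt * (k1E + 2.0 * k2E + 2.0 * k3E + k4E) / 6.0;
  I += dt * (k1I + 2.0 * k2I + 2.0 * k3I + k4I) / 6.0;
}

// [[Rcpp::export]]
NumericMatrix rk4_integrate_cpp(NumericVector params, NumericVector drive_E,
                                NumericVector drive_I, double duration,
                                double dt, double E0, double I0, int thin) {
  const double* p = params.begin();
  const double* dE_spec = drive_E.begin();
  const double* dI_spec = drive_I.begin();
  long n = (long)std::llround(duration / dt);
  long n_rec = n / thin + 1 + (n % thin != 0 ? 1 : 0);
  NumericMatrix out(n_rec, 5);
  double E = E0, I = I0;
  long r = 0;
  for (long i = 0; i <= n; ++i) {
    double t = i * dt;
    if (i % thin == 0 || i == n) {
      out(r, 0) = t;
      out(r, 1) = E;
      out(r, 2) = I;
      out(r, 3) = drive_at(dE_spec, t);
      out(r, 4) = drive_at(dI_spec, t);
      ++r;
    }
    if (i == n) break;
    rk4_step(E, I, t, dt, p, dE_spec, dI_spec);
    if (!std::isfinite(E) || !std::isfinite(I))
      stop("integration produced a non-finite state at t = %f", t + dt);
  }
  if (r < n_rec) out = out(Range(0, r - 1), Range(0, 4));
  colnames(out) = CharacterVector::create("t", "E", "I", "theta_E", "theta_I");
  return out;
}

// Post-transient extrema of E and I without storing the trajectory; used by
// envelope sweeps and two-parameter region maps.
// [[Rcpp::export]]
NumericVector rk4_extrema_cpp(NumericVector params, NumericVector drive_E,
                              NumericVector drive_I, double duration,
                              double dt, double E0, double I0,
                              double settle_fraction) {
  const double* p = params.begin();
  const double* dE_spec = drive_E.begin();
  const double* dI_spec = drive_I.begin();
  long n = (long)std::llround(duration / dt);
  long n_settle = (long)std::llround(settle_fraction * n);
  double E = E0, I = I0;
  double minE = R_PosInf, maxE = R_NegInf, minI = R_PosInf, maxI = R_NegInf;
  for (long i = 0; i <= n; ++i) {
    double t = i * dt;
    if (i >= n_settle) {
      if (E < minE) minE = E;
      if (E > maxE) maxE = E;
      if (I < minI) minI = I;
      if (I > maxI) maxI = I;
    }
    if (i == n) break;
    rk4_step(E, I, t, dt, p, dE_spec, dI_spec);
    if (!std::isfinite(E) || !std::isfinite(I))
      stop("integration produced a non-finite state at t = %f", t + dt);
  }
  return NumericVector::create(
      _["E_min"] = minE, _["E_max"] = maxE, _["I_min"] = minI,
      _["I_max"] = maxI, _["E_final"] = E, _["I_final"] = I);
}
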