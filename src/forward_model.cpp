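#include <Rcpp.h>
using namespace Rcpp;

// Exact convolution of a piecewise-linear signal x (uniform grid, step
// dt) with the kernel exp(-a s), via the closed-form one-step update
//   y[n+1] = E*y[n] + cA*x[n] + cB*x[n+1].
// Series expansions guard against cancellation for small a*dt; a = 0
// reduces to the cumulative trapezoid integral.
static void conv_exp_inplace(const double* x, int n, double dt, double a,
                             double coef, double* acc) {
  double E, I0, I1;
  double ad = a * dt;
  if (ad < 1e-6) {
    E = std::exp(-ad);
    I0 = dt * (1.0 - ad / 2.0 + ad * ad / 6.0 - ad * ad * ad / 24.0);
    I1 = dt * dt * (0.5 - ad / 3.0 + ad * ad / 8.0 - ad * ad * ad / 30.0);
  } else {
    E = std::exp(-ad);
    I0 = (1.0 - E) / a;
    I1 = (1.0 - E * (1.0 + ad)) / (a * a);
  }
  double cA = I1 / dt;
  double cB = I0 - I1 / dt;
  double y = 0.0;
  for (int i = 1; i < n; i++) {
    y = E * y + cA * x[i - 1] + cB * x[i];
    acc[i] += coef * y;
  }
}

// Evaluate the 2TCM / 2TCM-1K PET signal on the fine grid: the tissue
// impulse response phi1 e^{-a1 t} + phi2 e^{-a2 t} convolved with Cp,
// plus the blood (and, for the 1K model, irreversibly bound vascular)
// term.
// [[Rcpp::export]]
NumericVector cpp_forward_signal(NumericVector cp, NumericVector cwb,
                                 double dt, double K1, double k2, double k3,
                                 double k4, double Vb, double Kb,
                                 bool with_kb, bool blood_weighted) {
  int n = cp.size();
  NumericVector out(n);
  double s = k2 + k3 + k4;
  double disc = s * s - 4.0 * k2 * k4;
  disc = disc > 0 ? std::sqrt(disc) : 0.0;
  double a1 = (s - disc) / 2.0;
  double a2 = (s + disc) / 2.0;
  if (a2 - a1 < 1e-10) a2 = a1 + 1e-10;  // repeated-root guard
  double phi1 = K1 * (k3 + k4 - a1) / (a2 - a1);
  double phi2 = K1 * (a2 - k3 - k4) / (a2 - a1);

  std::vector<double> ct(n, 0.0);
  conv_exp_inplace(cp.begin(), n, dt, a1, phi1, ct.data());
  conv_exp_inplace(cp.begin(), n, dt, a2, phi2, ct.data());

  std::vector<double> cvasc(n, 0.0);
  if (with_kb && Kb > 0.0)
    conv_exp_inplace(cp.begin(), n, dt, 0.0, Kb, cvasc.data());

  for (int i = 0; i < n; i++) {
    double blood = blood_weighted ? Vb * (cwb[i] + cvasc[i])
                                  : Vb * cwb[i] + cvasc[i];
    out[i] = (1.0 - Vb) * ct[i] + blood;
  }
  return out;
}

// Frame-averaged model TAC for grid-aligned frame boundaries: the
// signal's cumulative trapezoid integral differenced at the 1-based
// boundary indices i0/i1 and divided by the frame durations.
// [[Rcpp::export]]
NumericVector cpp_forward_frames(NumericVector cp, NumericVector cwb,
                                 double dt, double K1, double k2, double k3,
                                 double k4, double Vb, double Kb,
                                 bool with_kb, bool blood_weighted,
                                 IntegerVector i0, IntegerVector i1,
                                 NumericVector durations) {
  NumericVector y = cpp_forward_signal(cp, cwb, dt, K1, k2, k3, k4, Vb, Kb,
                                       with_kb, blood_weighted);
  int n = y.size();
  std::vector<double> cum(n, 0.0);
  for (int i = 1; i < n; i++)
    cum[i] = cum[i - 1] + (y[i] + y[i - 1]) / 2.0 * dt;
  int nf = i0.size();
  NumericVector out(nf);
  for (int f = 0; f < nf; f++)
    out[f] = (cum[i1[f] - 1] - cum[i0[f] - 1]) / durations[f];
  return out;
}
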