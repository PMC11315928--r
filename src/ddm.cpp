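#include <Rcpp.h>
using namespace Rcpp;

// Defective first-passage CDF through the LOWER boundary (0) of a Wiener
// process with drift mu, diffusion coefficient 1, absorbing boundaries at
// 0 and a, started at w (evidence units, 0 < w < a). Decision time t.
//
// Large-time series (Cox-Miller form): for t > 0,
//   F0(t) = P0 - (2*pi/a^2) * sum_k k*sin(k*pi*w/a) *
//            exp(-mu*w - lam_k*t) / (mu^2 + k^2*pi^2/a^2),
//   lam_k = (mu^2 + k^2*pi^2/a^2)/2,
//   P0    = limiting absorption probability at 0.
// Terms are evaluated in exponent form so large |mu| cannot overflow.
static double wfpt_lower_cdf1(double t, double mu, double a, double w,
                              double tol, int kmax) {
  if (t <= 0.0) return 0.0;
  double p0;
  if (std::fabs(mu) < 1e-12) {
    p0 = (a - w) / a;
  } else if (mu > 0) {
    double em_w = std::exp(-2.0 * mu * w), em_a = std::exp(-2.0 * mu * a);
    p0 = (em_w - em_a) / (1.0 - em_a);
  } else {
    // multiply through by exp(2*mu*a): keeps exponents negative for mu < 0
    double e1 = std::exp(2.0 * mu * (a - w)), e2 = std::exp(2.0 * mu * a);
    p0 = (1.0 - e1) / (1.0 - e2);
  }
  const double pia = M_PI / a;
  double sum = 0.0;
  int small_run = 0;
  for (int k = 1; k <= kmax; ++k) {
    double kpia = k * pia;
    double denom = mu * mu + kpia * kpia;
    double lam = 0.5 * denom;
    double lg = -mu * w - lam * t;
    double term = (lg < -745.0) ? 0.0
      : k * std::sin(kpia * w) * std::exp(lg) / denom;
    sum += term;
    // sin() can vanish at individual k; require a run of small terms
    if (std::fabs(term) < tol) { if (++small_run >= 3) break; }
    else small_run = 0;
  }
  double f = p0 - (2.0 * M_PI / (a * a)) * sum;
  if (f < 0.0) f = 0.0;
  if (f > p0) f = p0;
  return f;
}

// [[Rcpp::export]]
NumericVector wfpt_cdf_core(NumericVector t, double mu, double a, double w,
                            bool upper, double tol, int kmax) {
  int n = t.size();
  NumericVector out(n);
  // upper-boundary absorption of (mu, start w) == lower-boundary absorption
  // of the reflected process (-mu, start a - w)
  double mu_ = upper ? -mu : mu;
  double w_  = upper ? a - w : w;
  for (int i = 0; i < n; ++i)
    out[i] = wfpt_lower_cdf1(t[i], mu_, a, w_, tol, kmax);
  return out;
}

// Euler-Maruyama sampler for n independent first-passage trials with
// Brownian-bridge boundary-crossing correction inside each step.
// Returns outcome (+1 upper, -1 lower, 0 unabsorbed by tmax) and the
// decision time of absorption (NA when unabsorbed). Uses R's RNG.
// [[Rcpp::export]]
List ddm_sample_core(int n, double a, double w0, double mu,
                     double dt, double tmax) {
  IntegerVector outcome(n);
  NumericVector dtime(n);
  for (int i = 0; i < n; ++i) {
    double x = w0, t = 0.0;
    int res = 0; double rt = NA_REAL;
    while (t < tmax - 1e-12) {
      // cap the final step so absorption times never exceed tmax
      double h = std::min(dt, tmax - t);
      double xn = x + mu * h + std::sqrt(h) * R::norm_rand();
      t += h;
      if (xn >= a) { res = 1; rt = t; break; }
      if (xn <= 0.0) { res = -1; rt = t; break; }
      // prob. the bridge between interior endpoints touched a boundary
      double pu = std::exp(-2.0 * (a - x) * (a - xn) / h);
      double pl = std::exp(-2.0 * x * xn / h);
      double u = R::unif_rand();
      if (u < pu) { res = 1; rt = t - 0.5 * h; break; }
      if (u < pl + pu) { res = -1; rt = t - 0.5 * h; break; }
      x = xn;
    }
    outcome[i] = res;
    dtime[i] = rt;
  }
  return List::create(_["outcome"] = outcome, _["dtime"] = dtime);
}
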