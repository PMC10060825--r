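#include <Rcpp.h>
using namespace Rcpp;

// Wiener first-passage-time machinery for a two-boundary diffusion with
// drift v, boundary separation a, relative start z (fraction of a) and
// diffusion coefficient s.  Densities are for the decision time (RT minus
// non-decision time).  The density of absorption at the LOWER boundary is
// computed directly; the upper-boundary density follows by the reflection
// (v, z) -> (-v, 1 - z).
//
// The dimensionless kernel f(tau | w) (a = 1, v = 0, s = 1) has two series
// representations; each trial is evaluated with whichever needs fewer terms
// at truncation tolerance `err` (both are available separately for
// cross-checking).

static const double PI_ = 3.141592653589793238462643383280;

// small-time expansion of the dimensionless kernel
static double fk_small(double tau, double w, double err) {
  // required number of terms (accuracy-based)
  double ks;
  if (2.0 * std::sqrt(2.0 * PI_ * tau) * err < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tau * std::log(2.0 * err * std::sqrt(2.0 * PI_ * tau)));
    ks = std::max(ks, std::sqrt(tau) + 1.0);
  } else {
    ks = 2.0;
  }
  int K = (int)std::ceil(ks);
  double sum = 0.0;
  for (int k = -K; k <= K; ++k) {
    double u = w + 2.0 * k;
    sum += u * std::exp(-u * u / (2.0 * tau));
  }
  return sum / std::sqrt(2.0 * PI_ * tau * tau * tau);
}

// large-time expansion of the dimensionless kernel
static double fk_large(double tau, double w, double err) {
  double kl;
  if (PI_ * tau * err < 1.0) {
    kl = std::sqrt(-2.0 * std::log(PI_ * tau * err) / (PI_ * PI_ * tau));
    kl = std::max(kl, 1.0 / (PI_ * std::sqrt(tau)));
  } else {
    kl = 1.0 / (PI_ * std::sqrt(tau));
  }
  int K = (int)std::ceil(kl);
  double sum = 0.0;
  for (int k = 1; k <= K; ++k) {
    sum += k * std::exp(-k * k * PI_ * PI_ * tau / 2.0) * std::sin(k * PI_ * w);
  }
  return PI_ * sum;
}

// term counts used to pick the cheaper branch
static bool small_is_cheaper(double tau, double err) {
  double ks, kl;
  if (2.0 * std::sqrt(2.0 * PI_ * tau) * err < 1.0) {
    ks = std::max(2.0 + std::sqrt(-2.0 * tau * std::log(2.0 * err * std::sqrt(2.0 * PI_ * tau))),
                  std::sqrt(tau) + 1.0);
  } else ks = 2.0;
  if (PI_ * tau * err < 1.0) {
    kl = std::max(std::sqrt(-2.0 * std::log(PI_ * tau * err) / (PI_ * PI_ * tau)),
                  1.0 / (PI_ * std::sqrt(tau)));
  } else kl = 1.0 / (PI_ * std::sqrt(tau));
  return ks < kl;
}

// density of absorption at the lower boundary at decision time t > 0.
// method: 0 = automatic branch choice, 1 = force small-time, 2 = force large-time
static double wfpt_lower(double t, double v, double a, double w,
                         double s, double err, int method) {
  if (!(t > 0.0)) return 0.0;
  double an = a / s, vn = v / s;            // reduce to s = 1
  double tau = t / (an * an);
  double kern;
  if (method == 1) kern = fk_small(tau, w, err);
  else if (method == 2) kern = fk_large(tau, w, err);
  else kern = small_is_cheaper(tau, err) ? fk_small(tau, w, err) : fk_large(tau, w, err);
  if (kern < 0.0) kern = 0.0;               // truncation can leave tiny negatives
  double lg = -vn * an * w - vn * vn * t / 2.0;
  return std::exp(lg) / (an * an) * kern;
}

// [[Rcpp::export(name = ".wfpt_density_cpp")]]
NumericVector wfpt_density_cpp(NumericVector t, double v, double a, double z,
                               double s, int upper, double err, int method) {
  int n = t.size();
  NumericVector out(n);
  double vv = upper ? -v : v;
  double ww = upper ? 1.0 - z : z;
  for (int i = 0; i < n; ++i) out[i] = wfpt_lower(t[i], vv, a, ww, s, err, method);
  return out;
}

// Negative log-likelihood of trial data under the multi-attribute DDM.
// par = (z, a, t0, dc, wm, wd); choice: 1 = LL (upper), 0 = SS (lower).
// Densities below `floor_dens` (including rt <= t0) are floored.
// [[Rcpp::export(name = ".ddm_nll_cpp")]]
double ddm_nll_cpp(NumericVector par, NumericVector money_diff,
                   NumericVector delay_diff, IntegerVector choice,
                   NumericVector rt, double s, double floor_dens, double err) {
  double z = par[0], a = par[1], t0 = par[2];
  double dc = par[3], wm = par[4], wd = par[5];
  if (!(a > 0.0) || !(z > 0.0) || !(z < 1.0) || t0 < 0.0) return R_PosInf;
  int n = rt.size();
  double nll = 0.0;
  for (int i = 0; i < n; ++i) {
    double v = dc + wm * money_diff[i] + wd * delay_diff[i];
    double td = rt[i] - t0;
    double dens;
    if (td <= 0.0) {
      dens = floor_dens;
    } else if (choice[i] == 1) {
      dens = wfpt_lower(td, -v, a, 1.0 - z, s, err, 0);
    } else {
      dens = wfpt_lower(td, v, a, z, s, err, 0);
    }
    if (dens < floor_dens) dens = floor_dens;
    nll -= std::log(dens);
  }
  return nll;
}

// Euler-Maruyama simulation of the diffusion with a Brownian-bridge
// crossing correction inside each step (removes the O(sqrt(dt)) boundary
// bias of the naive scheme).  Returns choice (1 = upper/LL, 0 = lower/SS,
// NA = censored at `cap` seconds of decision time) and rt = crossing time
// plus t0.  Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export(name = ".sim_ddm_cpp")]]
List sim_ddm_cpp(NumericVector v, double a, double z, double t0,
                 double s, double dt, double cap) {
  int n = v.size();
  IntegerVector choice(n);
  NumericVector rt(n);
  LogicalVector censored(n);
  double sdt = s * std::sqrt(dt);
  // beyond this distance from a boundary the bridge crossing prob < 1e-16
  double guard = 6.1 * sdt;
  for (int i = 0; i < n; ++i) {
    double x = z * a;
    double t = 0.0;
    double drift_dt = v[i] * dt;
    int ch = NA_INTEGER;
    bool done = false;
    while (!done) {
      double xn = x + drift_dt + sdt * norm_rand();
      t += dt;
      if (xn >= a) { ch = 1; done = true; }
      else if (xn <= 0.0) { ch = 0; done = true; }
      else {
        if (a - x < guard || a - xn < guard) {
          double p = std::exp(-2.0 * (a - x) * (a - xn) / (s * s * dt));
          if (unif_rand() < p) { ch = 1; done = true; }
        }
        if (!done && (x < guard || xn < guard)) {
          double p = std::exp(-2.0 * x * xn / (s * s * dt));
          if (unif_rand() < p) { ch = 0; done = true; }
        }
      }
      if (!done && t >= cap) { censored[i] = true; break; }
      x = xn;
    }
    choice[i] = ch;
    rt[i] = t + t0;
  }
  return List::create(_["choice"] = choice, _["rt"] = rt,
                      _["censored"] = censored);
}
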