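#include <Rcpp.h>
using namespace Rcpp;

// One-dimensional double-well attractor dynamics.
//
// Within a trial the decision variable x follows
//   dx = -V'(x) dt / tau_trial + sigma sqrt(dt) eta,
// with the quartic landscape V(x, c) = x^4/4 - x^2/2 - c x, so
//   -V'(x) = -x^3 + x + c.
// During the inter-trial interval the inputs are off and x relaxes linearly
// toward the neutral point:
//   dx = -(x / tau_iti) dt + sigma_iti sqrt(dt) eta.
// Euler-Maruyama with fixed dt; noise drawn from R's RNG so that set.seed()
// on the R side makes every run reproducible.

static inline double clip(double x, double ceiling) {
  if (x > ceiling) return ceiling;
  if (x < -ceiling) return -ceiling;
  return x;
}

// [[Rcpp::export]]
double cpp_relax_iti(double x0, double duration, double sigma_iti,
                     double dt, double tau_iti) {
  if (duration <= 0.0) return x0;
  int n = (int) std::floor(duration / dt + 1e-9);
  double x = x0;
  double sqdt = std::sqrt(dt);
  for (int i = 0; i < n; ++i) {
    double eta = (sigma_iti > 0.0) ? norm_rand() : 0.0;
    x += -(x / tau_iti) * dt + sigma_iti * sqdt * eta;
  }
  return x;
}

// [[Rcpp::export]]
List cpp_run_trial(double x0, double c, double sigma, double threshold,
                   double dt, double tau_trial, double t_max,
                   double ceiling) {
  double x = x0;
  double t = 0.0;
  double sqdt = std::sqrt(dt);
  double rate = dt / tau_trial;
  int choice = 0; // +1 SN, -1 LF, 0 timeout
  while (t < t_max) {
    double eta = (sigma > 0.0) ? norm_rand() : 0.0;
    x += (-x * x * x + x + c) * rate + sigma * sqdt * eta;
    x = clip(x, ceiling);
    t += dt;
    if (std::fabs(x) >= threshold) {
      choice = (x > 0) ? 1 : -1;
      break;
    }
  }
  return List::create(_["choice"] = choice, _["rt"] = t, _["end_x"] = x);
}

// [[Rcpp::export]]
DataFrame cpp_simulate_sequence(NumericVector c_values, double x0,
                                double sigma, double sigma_iti,
                                double threshold, double dt,
                                double tau_trial, double tau_iti,
                                double t_max, double iti_duration,
                                double ceiling) {
  int n = c_values.size();
  IntegerVector choice(n);
  NumericVector rt(n), end_x(n);
  double x = x0;
  for (int i = 0; i < n; ++i) {
    x = cpp_relax_iti(x, iti_duration, sigma_iti, dt, tau_iti);
    List out = cpp_run_trial(x, c_values[i], sigma, threshold, dt,
                             tau_trial, t_max, ceiling);
    choice[i] = out["choice"];
    rt[i] = out["rt"];
    end_x[i] = out["end_x"];
    x = end_x[i];
  }
  return DataFrame::create(_["choice"] = choice, _["rt"] = rt,
                           _["end_x"] = end_x);
}
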