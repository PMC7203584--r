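#include <Rcpp.h>
using namespace Rcpp;

// Interactive-activation settling loop of the PCS network. Mirrors the R
// implementation in pcs_step()/pcs_energy() exactly (same update order and
// stopping rule); exists only because the chooser runs it tens of
// thousands of times per cohort.

// [[Rcpp::export]]
List cpp_pcs_settle(NumericMatrix W, NumericVector a0, double decay,
                    double floor_, double ceiling, double stability,
                    int max_iters) {
  int n = a0.size();
  std::vector<double> a(a0.begin(), a0.end());
  std::vector<double> net(n);
  // energy E = a' W a / 2 (W symmetric, zero diagonal)
  auto energy = [&]() {
    double e = 0.0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        e += W(i, j) * a[i] * a[j];
    return e;
  };
  double e_prev = energy();
  int iters = 0;
  bool converged = false;
  while (iters < max_iters) {
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j < n; ++j) s += W(i, j) * a[j];
      net[i] = s;
    }
    for (int i = 1; i < n; ++i) { // node 0 (validity) stays clamped
      double up = a[i] * (1.0 - decay) +
        (net[i] > 0 ? net[i] * (ceiling - a[i]) : net[i] * (a[i] - floor_));
      a[i] = std::min(std::max(up, floor_), ceiling);
    }
    ++iters;
    double e = energy();
    if (std::fabs(e - e_prev) < stability) {
      converged = true;
      break;
    }
    e_prev = e;
  }
  return List::create(_["a"] = NumericVector(a.begin(), a.end()),
                      _["iterations"] = iters,
                      _["converged"] = converged);
}
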