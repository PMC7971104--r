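#include <Rcpp.h>
using namespace Rcpp;

// Weighted circular-binary-segmentation split search.
//
// For a signal x with positional weights w, every circular arc is described
// by a boundary pair (i, j), 0 <= i < j <= n, the arc being positions
// i+1..j (1-based).  The two-sample statistic between arc and complement
// treats x_k ~ N(mu_group, sigma^2 / w_k):
//
//   d   = S1/W1 - S0/W0            (weighted group means)
//   B   = d^2 * W1 * W0 / Wtot     (between-group weighted SS)
//   T^2 = B * (n - 2) / (TSS - B)  (TSS = total weighted SS about the mean)
//
// TSS is fixed for a given value assignment, so the argmax over arcs can be
// found on B alone; T itself is needed to compare across permutations
// because permuting the values changes TSS when weights differ by position.

static double max_arc_T(const std::vector<double> &x,
                        const NumericVector &w,
                        int n, int min_width, double Wtot,
                        int *best_i, int *best_j) {
  std::vector<double> cw(n + 1, 0.0), cs(n + 1, 0.0);
  double sxx = 0.0;
  for (int k = 0; k < n; ++k) {
    cw[k + 1] = cw[k] + w[k];
    cs[k + 1] = cs[k] + w[k] * x[k];
    sxx += w[k] * x[k] * x[k];
  }
  const double Stot = cs[n];
  const double TSS = sxx - Stot * Stot / Wtot;
  double bestB = -1.0;
  int bi = -1, bj = -1;
  for (int i = 0; i <= n - 1; ++i) {
    for (int j = i + 1; j <= n; ++j) {
      int la = j - i;
      if (la < min_width || n - la < min_width) continue;
      double W1 = cw[j] - cw[i];
      double W0 = Wtot - W1;
      if (W1 <= 0.0 || W0 <= 0.0) continue;
      double S1 = cs[j] - cs[i];
      double d = S1 / W1 - (Stot - S1) / W0;
      double B = d * d * W1 * W0 / Wtot;
      if (B > bestB) { bestB = B; bi = i; bj = j; }
    }
  }
  if (bi < 0) return 0.0;
  if (best_i) *best_i = bi;
  if (best_j) *best_j = bj;
  double denom = TSS - bestB;
  if (denom <= 1e-300) return 1e12;  // split explains everything
  return std::sqrt(bestB * (n - 2) / denom);
}

// [[Rcpp::export]]
List cbs_best_split_cpp(NumericVector x, NumericVector w,
                        int min_width, int n_perm, double alpha,
                        bool early_stop = true) {
  const int n = x.size();
  if (w.size() != n) stop("length(x) != length(w)");
  if (n < 2 * min_width) stop("signal shorter than 2*min_width");
  double Wtot = 0.0;
  for (int k = 0; k < n; ++k) {
    if (w[k] <= 0.0) stop("weights must be positive");
    Wtot += w[k];
  }
  std::vector<double> xs(x.begin(), x.end());
  int bi = -1, bj = -1;
  const double T_obs = max_arc_T(xs, w, n, min_width, Wtot, &bi, &bj);

  // permutation of values over positions, weights fixed; sequential early
  // stop once the exceedance count already forces p > alpha
  int exceed = 0, done = 0;
  const int stop_at = (int)std::ceil(alpha * n_perm);
  for (int b = 0; b < n_perm; ++b) {
    for (int k = n - 1; k > 0; --k) {
      int m = (int)(unif_rand() * (k + 1));
      if (m > k) m = k;
      std::swap(xs[k], xs[m]);
    }
    double T = max_arc_T(xs, w, n, min_width, Wtot, nullptr, nullptr);
    if (T >= T_obs) ++exceed;
    ++done;
    if (early_stop && exceed > stop_at) break;
  }
  return List::create(_["i"] = bi, _["j"] = bj, _["t"] = T_obs,
                      _["p"] = (double)exceed / (double)done,
                      _["n_perm_used"] = done);
}
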