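#include <Rcpp.h>
using namespace Rcpp;

// Standard-normal quantile, Acklam's rational approximation (|abs err| < 8e-9;
// negligible against Monte Carlo noise at the population sizes used here).
// Draws flow through R's unif_rand() so that .Random.seed / L'Ecuyer-CMRG
// substreams fully determine every simulated individual.
static inline double inv_norm(double u) {
  static const double a[] = {-3.969683028665376e+01,  2.209460984245205e+02,
                             -2.759285104469687e+02,  1.383577518672690e+02,
                             -3.066479806614716e+01,  2.506628277459239e+00};
  static const double b[] = {-5.447609879822406e+01,  1.615858368580409e+02,
                             -1.556989798598866e+02,  6.680131188771972e+01,
                             -1.328068155288572e+01};
  static const double c[] = {-7.784894002430293e-03, -3.223964580411365e-01,
                             -2.400758277161838e+00, -2.549732539343734e+00,
                              4.374664141464968e+00,  2.938163982698783e+00};
  static const double d[] = { 7.784695709041462e-03,  3.224671290700398e-01,
                              2.445134137142996e+00,  3.754408661907416e+00};
  const double plow = 0.02425, phigh = 1.0 - plow;
  double q, x;
  if (u < plow) {
    q = std::sqrt(-2.0 * std::log(u));
    x = (((((c[0]*q + c[1])*q + c[2])*q + c[3])*q + c[4])*q + c[5]) /
        ((((d[0]*q + d[1])*q + d[2])*q + d[3])*q + 1.0);
  } else if (u <= phigh) {
    q = u - 0.5;
    double r = q * q;
    x = (((((a[0]*r + a[1])*r + a[2])*r + a[3])*r + a[4])*r + a[5]) * q /
        (((((b[0]*r + b[1])*r + b[2])*r + b[3])*r + b[4])*r + 1.0);
  } else {
    q = std::sqrt(-2.0 * std::log(1.0 - u));
    x = -(((((c[0]*q + c[1])*q + c[2])*q + c[3])*q + c[4])*q + c[5]) /
         ((((d[0]*q + d[1])*q + d[2])*q + d[3])*q + 1.0);
  }
  return x;
}

// Simulate n individuals over a topologically ordered linear-Gaussian DAG.
// parents[j] holds 0-based indices of node j's parents (all < j),
// weights[j] the matching edge weights, noise_sd[j] the noise scale chosen
// so each node has unit marginal variance. Noise draws are interleaved per
// individual (node order within individual), which defines the stream layout.
// [[Rcpp::export]]
List dag_sim_kernel(int n, List parents, List weights, NumericVector noise_sd) {
  const int k = noise_sd.size();
  // flatten the parent structure for a tight inner loop
  std::vector<int> off(k + 1, 0);
  for (int j = 0; j < k; ++j) {
    off[j + 1] = off[j] + Rf_length(parents[j]);
  }
  std::vector<int> pa(off[k]);
  std::vector<double> wt(off[k]);
  for (int j = 0; j < k; ++j) {
    IntegerVector pj = parents[j];
    NumericVector wj = weights[j];
    for (int m = 0; m < pj.size(); ++m) {
      pa[off[j] + m] = pj[m];
      wt[off[j] + m] = wj[m];
    }
  }
  List out(k);
  std::vector<double*> col(k);
  for (int j = 0; j < k; ++j) {
    NumericVector v(n);
    out[j] = v;
    col[j] = REAL(v);
  }
  const int *pa_ = pa.data();
  const double *wt_ = wt.data();
  const double *sd_ = REAL(noise_sd);
  std::vector<double> vals(k);
  double *v_ = vals.data();
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < k; ++j) {
      double acc = 0.0;
      for (int m = off[j]; m < off[j + 1]; ++m) acc += wt_[m] * v_[pa_[m]];
      v_[j] = acc + sd_[j] * inv_norm(unif_rand());
      col[j][i] = v_[j];
    }
  }
  return out;
}

// Bernoulli selection with logistic link: for each individual,
// Pr(s = 1) = expit(alpha + sum_k coefs[k] * cols[k][i]).
// cols may be empty (pure Bernoulli(expit(alpha)) selection).
// Returns the 0/1 indicator plus the (1-based) indices of selected
// individuals, collected for free during the draw loop.
// [[Rcpp::export]]
List selection_kernel(List cols, NumericVector coefs, double alpha, int n) {
  const int m = coefs.size();
  std::vector<const double*> x(m);
  for (int j = 0; j < m; ++j) {
    NumericVector v = cols[j];
    if (v.size() != n) stop("selection covariate length mismatch");
    x[j] = REAL(v);
  }
  IntegerVector s(n);
  int *s_ = INTEGER(s);
  const double *b_ = REAL(coefs);
  std::vector<int> idx;
  idx.reserve(n / 8);
  RNGScope scope;
  if (m == 2) {  // common case: phenotype + outcome
    const double b0 = b_[0], b1 = b_[1];
    const double *x0 = x[0], *x1 = x[1];
    for (int i = 0; i < n; ++i) {
      double pr = 1.0 / (1.0 + std::exp(-(alpha + b0 * x0[i] + b1 * x1[i])));
      if (unif_rand() < pr) { s_[i] = 1; idx.push_back(i + 1); } else s_[i] = 0;
    }
  } else {
    for (int i = 0; i < n; ++i) {
      double lp = alpha;
      for (int j = 0; j < m; ++j) lp += b_[j] * x[j][i];
      double pr = 1.0 / (1.0 + std::exp(-lp));
      if (unif_rand() < pr) { s_[i] = 1; idx.push_back(i + 1); } else s_[i] = 0;
    }
  }
  return List::create(_["s"] = s, _["idx"] = wrap(idx));
}
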