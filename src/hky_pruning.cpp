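#include <Rcpp.h>
using namespace Rcpp;

// Felsenstein pruning log-likelihood for a fixed genealogy under a
// reversible 4-state substitution model supplied as an eigendecomposition
// (V, Vi, lambda) of the normalised rate matrix, with stationary
// frequencies pi at the root.
//
// edges: E x 2 integer matrix (parent, child), 1-based node ids with tips
//   1..n_tips, sorted so that every child's own incoming edges appear
//   before the edge where it is the child (sort by parent node time).
// elen: branch lengths in expected substitutions per site.
// tip_pat: n_tips x P integer matrix of states 1..4 (0 = missing).
// weights: pattern counts.
// [[Rcpp::export]]
double hky_pruning_loglik(IntegerMatrix edges, NumericVector elen,
                          IntegerMatrix tip_pat, NumericVector weights,
                          NumericMatrix V, NumericMatrix Vi,
                          NumericVector lambda, NumericVector pi,
                          int n_nodes, int root) {
  const int E = edges.nrow();
  const int P = tip_pat.ncol();
  const int n_tips = tip_pat.nrow();

  // partial likelihoods, n_nodes x 4 x P, plus per-node log scalers
  std::vector<double> part((size_t)n_nodes * 4 * P, 1.0);
  std::vector<double> logscale(n_nodes, 0.0);
  std::vector<bool> touched(n_nodes, false);

  // initialise tips
  for (int v = 0; v < n_tips; ++v) {
    double *pv = &part[(size_t)v * 4 * P];
    for (int s = 0; s < P; ++s) {
      int st = tip_pat(v, s);
      if (st > 0) {
        for (int i = 0; i < 4; ++i) pv[i * P + s] = (i == st - 1) ? 1.0 : 0.0;
      }
    }
    touched[v] = true;
  }

  double Pm[16];
  for (int e = 0; e < E; ++e) {
    int p = edges(e, 0) - 1, c = edges(e, 1) - 1;
    double t = elen[e];
    // P(t) = V diag(exp(lambda t)) Vi
    double ev[4];
    for (int i = 0; i < 4; ++i) ev[i] = std::exp(lambda[i] * t);
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j) {
        double s = 0.0;
        for (int k = 0; k < 4; ++k) s += V(i, k) * ev[k] * Vi(k, j);
        Pm[i * 4 + j] = s > 0.0 ? s : 0.0;
      }
    double *pc = &part[(size_t)c * 4 * P];
    double *pp = &part[(size_t)p * 4 * P];
    if (!touched[p]) touched[p] = true;
    double mx = 0.0;
    for (int s = 0; s < P; ++s) {
      double msg[4];
      for (int i = 0; i < 4; ++i) {
        double sum = 0.0;
        for (int j = 0; j < 4; ++j) sum += Pm[i * 4 + j] * pc[j * P + s];
        msg[i] = sum;
      }
      for (int i = 0; i < 4; ++i) {
        double val = pp[i * P + s] * msg[i];
        pp[i * P + s] = val;
        if (val > mx) mx = val;
      }
    }
    logscale[p] += logscale[c];
    logscale[c] = 0.0;  // consumed
    // rescale parent to avoid underflow
    if (mx > 0.0 && (mx < 1e-100 || mx > 1e100)) {
      for (int s = 0; s < P * 4; ++s) pp[s] /= mx;
      logscale[p] += std::log(mx);
    }
  }

  // per-pattern scaling at the root
  double ll = 0.0;
  double *pr = &part[(size_t)(root - 1) * 4 * P];
  for (int s = 0; s < P; ++s) {
    double sum = 0.0;
    for (int i = 0; i < 4; ++i) sum += pi[i] * pr[i * P + s];
    if (sum <= 0.0) return R_NegInf;
    ll += weights[s] * std::log(sum);
  }
  return ll + logscale[root - 1];
}
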