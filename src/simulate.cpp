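#include <Rcpp.h>
using namespace Rcpp;

// Forward-sample a coupled point-process GLM, bin by bin.
//
// alpha0: per-cell baseline log-rates (log spikes/s).
// A:      C x (C*K) coefficient matrix, columns source-cell major
//         (source 1 windows 1..K, source 2 windows 1..K, ...).
// win_lo/win_hi: inclusive lag ranges in bins (>= 1, strictly causal).
//
// Per bin, each cell spikes independently with probability
// exp(eta) * delta given the shared sampled history; the probability is
// clipped at 1 - 1e-6 and clip events are counted.  Uses R's RNG, so
// set.seed() on the R side makes runs bit-reproducible.
// [[Rcpp::export]]
List simulate_trials_cpp(int n_trials, int n_bins, double delta,
                         NumericVector alpha0, NumericMatrix A,
                         IntegerVector win_lo, IntegerVector win_hi) {
  const int C = alpha0.size();
  const int K = win_lo.size();
  if (A.nrow() != C || A.ncol() != C * K)
    stop("coefficient matrix must be C x (C*K)");
  const double clip = 1.0 - 1e-6;
  double clipped = 0.0;
  List trials(n_trials);
  std::vector<int> B((size_t)C * n_bins);
  std::vector<double> x((size_t)C * K);

  for (int tr = 0; tr < n_trials; ++tr) {
    std::fill(B.begin(), B.end(), 0);
    std::vector< std::vector<int> > spikes(C);
    for (int t = 0; t < n_bins; ++t) {
      // lagged spike counts from history strictly before bin t
      for (int i = 0; i < C; ++i) {
        const int* Bi = &B[(size_t)i * n_bins];
        for (int k = 0; k < K; ++k) {
          int lo = t - win_hi[k];
          int hi = t - win_lo[k];
          int cnt = 0;
          for (int u = lo < 0 ? 0 : lo; u <= hi; ++u) cnt += Bi[u];
          x[(size_t)i * K + k] = cnt;
        }
      }
      for (int c = 0; c < C; ++c) {
        double eta = alpha0[c];
        for (int j = 0; j < C * K; ++j)
          if (x[j] != 0.0) eta += A(c, j) * x[j];
        double p = std::exp(eta) * delta;
        if (!std::isfinite(p))
          stop("numerical-failure: non-finite lambda (trial %d, bin %d, cell %d, eta = %f)",
               tr + 1, t + 1, c + 1, eta);
        if (p > clip) { p = clip; clipped += 1.0; }
        if (unif_rand() < p) {
          B[(size_t)c * n_bins + t] = 1;
          spikes[c].push_back(t + 1);
        }
      }
    }
    List cell_spikes(C);
    for (int c = 0; c < C; ++c) cell_spikes[c] = wrap(spikes[c]);
    trials[tr] = cell_spikes;
  }
  return List::create(_["trials"] = trials, _["n_clipped"] = clipped);
}
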