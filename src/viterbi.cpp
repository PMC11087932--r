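#include <Rcpp.h>
using namespace Rcpp;

// Viterbi decoding for a single chromosome run.
//
// emis: n x K matrix of per-bin log emission densities (state prior already
// added by the caller). Transitions are homogeneous: log_self on the
// diagonal, log_switch off-diagonal. Initial distribution is uniform.
// Returns the maximum-probability state path (1-based column indices) and
// its joint log probability.
// [[Rcpp::export]]
List viterbi_decode(NumericMatrix emis, double log_self, double log_switch) {
  const int n = emis.nrow();
  const int K = emis.ncol();
  if (n == 0) stop("empty emission matrix");

  NumericMatrix delta(n, K);
  IntegerMatrix psi(n, K);
  const double log_init = -std::log((double)K);

  for (int k = 0; k < K; ++k) {
    delta(0, k) = log_init + emis(0, k);
    psi(0, k) = 0;
  }
  for (int i = 1; i < n; ++i) {
    for (int j = 0; j < K; ++j) {
      double best = R_NegInf;
      int arg = 0;
      for (int k = 0; k < K; ++k) {
        double cand = delta(i - 1, k) + (k == j ? log_self : log_switch);
        if (cand > best) {
          best = cand;
          arg = k;
        }
      }
      delta(i, j) = best + emis(i, j);
      psi(i, j) = arg;
    }
  }

  IntegerVector path(n);
  double best = R_NegInf;
  int arg = 0;
  for (int k = 0; k < K; ++k) {
    if (delta(n - 1, k) > best) {
      best = delta(n - 1, k);
      arg = k;
    }
  }
  path[n - 1] = arg + 1;
  for (int i = n - 1; i > 0; --i) {
    arg = psi(i, arg);
    path[i - 1] = arg + 1;
  }
  return List::create(_["path"] = path, _["log_likelihood"] = best);
}
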