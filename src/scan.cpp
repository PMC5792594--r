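#include <Rcpp.h>
using namespace Rcpp;

// Best ungapped window score of a position-specific score matrix (20 x L,
// rows in alphabetical amino-acid order) along an integer-coded sequence.
// Returns score = -Inf and start = -1 when no placement fits.
// [[Rcpp::export]]
List cpp_best_window(IntegerVector seq, NumericMatrix prof) {
  const int L = prof.ncol();
  const int N = seq.size();
  if (N < L) {
    return List::create(_["score"] = R_NegInf, _["start"] = -1);
  }
  double best = R_NegInf;
  int best_i = -1;
  for (int i = 0; i + L <= N; ++i) {
    double s = 0.0;
    for (int j = 0; j < L; ++j) {
      s += prof(seq[i + j], j);
    }
    if (s > best) {
      best = s;
      best_i = i;
    }
  }
  return List::create(_["score"] = best, _["start"] = best_i);
}

// Best-window scores of n_shuffles random permutations of the sequence;
// permutations are supplied pre-drawn from R so the RNG stays under R's
// seed control. perms is an (n_shuffles x N) matrix of 0-based indices.
// [[Rcpp::export]]
NumericVector cpp_null_scores(IntegerVector seq, NumericMatrix prof,
                              IntegerMatrix perms) {
  const int L = prof.ncol();
  const int N = seq.size();
  const int B = perms.nrow();
  NumericVector out(B);
  std::vector<int> shuf(N);
  for (int b = 0; b < B; ++b) {
    for (int k = 0; k < N; ++k) shuf[k] = seq[perms(b, k)];
    double best = R_NegInf;
    for (int i = 0; i + L <= N; ++i) {
      double s = 0.0;
      for (int j = 0; j < L; ++j) s += prof(shuf[i + j], j);
      if (s > best) best = s;
    }
    out[b] = best;
  }
  return out;
}
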