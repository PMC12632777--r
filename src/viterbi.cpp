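#include <Rcpp.h>
using namespace Rcpp;

// Generic log-space Viterbi: emis (m sites x S states) per-site emission
// log-likelihoods, ltrans a list of m-1 S x S log-transition matrices
// (rows = previous state, cols = current). Uniform initial distribution;
// ties broken toward the smallest state index. Returns the 1-based
// argmax state path.
// [[Rcpp::export]]
IntegerVector viterbi_cpp(NumericMatrix emis, List ltrans) {
  const int m = emis.nrow(), S = emis.ncol();
  if (ltrans.size() != m - 1) stop("need one transition matrix per interval");
  std::vector<double> delta(S), ndelta(S);
  IntegerMatrix bp(m, S);
  const double lupi = -std::log((double) S);
  for (int j = 0; j < S; ++j) delta[j] = emis(0, j) + lupi;
  for (int t = 1; t < m; ++t) {
    NumericMatrix lt = ltrans[t - 1];
    if (lt.nrow() != S || lt.ncol() != S) stop("transition matrix shape");
    for (int j = 0; j < S; ++j) {
      double best = delta[0] + lt(0, j);
      int arg = 0;
      for (int i = 1; i < S; ++i) {
        double v = delta[i] + lt(i, j);
        if (v > best) { best = v; arg = i; }
      }
      ndelta[j] = best + emis(t, j);
      bp(t, j) = arg;
    }
    delta = ndelta;
  }
  int last = 0;
  for (int j = 1; j < S; ++j) if (delta[j] > delta[last]) last = j;
  IntegerVector path(m);
  path[m - 1] = last + 1;
  for (int t = m - 1; t > 0; --t) {
    last = bp(t, last);
    path[t - 1] = last + 1;
  }
  return path;
}
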