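#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Stack-only nested-structure MFE folding of a single RNA strand.
// Only stacked pair steps carry energy (isolated pairs score 0, loops are
// free), no pseudoknots, minimum hairpin loop of 3 unpaired nucleotides.
// Used by the accessibility backend: the same DP is run with and without the
// target-site positions allowed to pair.
//
// s: nucleotide codes 1..4 (A,C,G,U); can: per-position pairing permission;
// stk: 6x6 stack energy table indexed by pair type of (i,j) then (i+1,j-1),
// pair types 1 A:U, 2 C:G, 3 G:C, 4 U:A, 5 G:U, 6 U:G.

static inline int pair_type(int a, int b) {
  if (a == 1 && b == 4) return 1;
  if (a == 2 && b == 3) return 2;
  if (a == 3 && b == 2) return 3;
  if (a == 4 && b == 1) return 4;
  if (a == 3 && b == 4) return 5;
  if (a == 4 && b == 3) return 6;
  return 0;
}

// [[Rcpp::export]]
double fold_mfe_cpp(IntegerVector s, LogicalVector can, NumericMatrix stk,
                    int minloop = 3) {
  const int n = s.size();
  if (can.size() != n) stop("fold_mfe_cpp: length mismatch");
  if (n < minloop + 2) return 0.0;
  const double INF = 1e9;
  std::vector<double> C((size_t)n * n, INF), W((size_t)n * n, 0.0);

  for (int len = minloop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int t = pair_type(s[i], s[j]);
      double c = INF;
      if (t > 0 && can[i] && can[j]) {
        c = W[(size_t)(i + 1) * n + (j - 1)];
        double cin = C[(size_t)(i + 1) * n + (j - 1)];
        if (cin < INF / 2) {
          int t2 = pair_type(s[i + 1], s[j - 1]);
          double alt = cin + stk(t - 1, t2 - 1);
          if (alt < c) c = alt;
        }
      }
      C[(size_t)i * n + j] = c;
      double w = std::min(W[(size_t)(i + 1) * n + j],
                          W[(size_t)i * n + (j - 1)]);
      if (c < w) w = c;
      for (int k = i; k < j; ++k) {
        double v = W[(size_t)i * n + k] + W[(size_t)(k + 1) * n + j];
        if (v < w) w = v;
      }
      if (w > 0) w = 0;
      W[(size_t)i * n + j] = w;
    }
  }
  return W[(size_t)0 * n + (n - 1)];
}
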