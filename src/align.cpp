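#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap penalty.
// Scoring: match +1, mismatch -1, gap -2 per gapped position.
// Returns matched positions and total alignment length, from which
// identity = matches / alignment_length.
//
// Only the counts are needed downstream, so the traceback stores
// move directions in a byte matrix (0 diag, 1 up, 2 left).
// [[Rcpp::export(name = ".nw_identity_cpp")]]
NumericVector nw_identity_cpp(std::string a, std::string b) {
  const int n = a.size(), m = b.size();
  const double MATCH = 1.0, MISMATCH = -1.0, GAP = -2.0;
  if (n == 0 || m == 0) {
    return NumericVector::create(_["matches"] = 0.0,
                                 _["length"] = (double)(n + m));
  }
  std::vector<double> prev(m + 1), cur(m + 1);
  std::vector<unsigned char> tb((n + 1) * (m + 1), 0);
  for (int j = 0; j <= m; ++j) { prev[j] = GAP * j; tb[j] = 2; }
  tb[0] = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = GAP * i;
    tb[i * (m + 1)] = 1;
    for (int j = 1; j <= m; ++j) {
      double sdiag = prev[j - 1] + (a[i - 1] == b[j - 1] ? MATCH : MISMATCH);
      double sup = prev[j] + GAP;
      double sleft = cur[j - 1] + GAP;
      // tie preference: diag, then up, then left (deterministic)
      double best = sdiag; unsigned char mv = 0;
      if (sup > best) { best = sup; mv = 1; }
      if (sleft > best) { best = sleft; mv = 2; }
      cur[j] = best;
      tb[i * (m + 1) + j] = mv;
    }
    std::swap(prev, cur);
  }
  // traceback
  int i = n, j = m;
  double matches = 0.0, len = 0.0;
  while (i > 0 || j > 0) {
    unsigned char mv = tb[i * (m + 1) + j];
    if (i > 0 && j > 0 && mv == 0) {
      if (a[i - 1] == b[j - 1]) matches += 1.0;
      --i; --j;
    } else if (i > 0 && (mv == 1 || j == 0)) {
      --i;
    } else {
      --j;
    }
    len += 1.0;
  }
  return NumericVector::create(_["matches"] = matches, _["length"] = len);
}
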