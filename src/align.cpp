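// Minimum-edit word alignment with canonical counts: among all unit-cost
// minimum-edit alignments the one maximizing matched (correct) words is
// taken, which makes the C/S/I/D counts unique and symmetric under swapping
// reference and hypothesis (insertions and deletions exchange roles).
#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// [[Rcpp::export(name = ".word_align")]]
std::string word_align(CharacterVector ref, CharacterVector hyp) {
  const int n = ref.size(), m = hyp.size();
  std::vector<std::string> a(n), b(m);
  for (int i = 0; i < n; ++i) a[i] = as<std::string>(ref[i]);
  for (int j = 0; j < m; ++j) b[j] = as<std::string>(hyp[j]);

  const int W = m + 1;
  std::vector<int> cost((n + 1) * W), hits((n + 1) * W);
  std::vector<unsigned char> mv((n + 1) * W);  // 0 diag, 1 del(up), 2 ins(left)
  for (int j = 0; j <= m; ++j) { cost[j] = j; hits[j] = 0; mv[j] = 2; }
  for (int i = 1; i <= n; ++i) {
    cost[i * W] = i; hits[i * W] = 0; mv[i * W] = 1;
    for (int j = 1; j <= m; ++j) {
      const bool eq = a[i - 1] == b[j - 1];
      int c = cost[(i - 1) * W + (j - 1)] + (eq ? 0 : 1);
      int h = hits[(i - 1) * W + (j - 1)] + (eq ? 1 : 0);
      unsigned char k = 0;
      const int cd = cost[(i - 1) * W + j] + 1, hd = hits[(i - 1) * W + j];
      if (cd < c || (cd == c && hd > h)) { c = cd; h = hd; k = 1; }
      const int ci = cost[i * W + (j - 1)] + 1, hi = hits[i * W + (j - 1)];
      if (ci < c || (ci == c && hi > h)) { c = ci; h = hi; k = 2; }
      cost[i * W + j] = c; hits[i * W + j] = h; mv[i * W + j] = k;
    }
  }
  std::string ops;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const unsigned char k = mv[i * W + j];
    if (k == 0 && i > 0 && j > 0) {
      ops.push_back(a[i - 1] == b[j - 1] ? 'M' : 'S'); --i; --j;
    } else if (k == 1 && i > 0) { ops.push_back('D'); --i; }
    else { ops.push_back('I'); --j; }
  }
  std::reverse(ops.begin(), ops.end());
  return ops;
}
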