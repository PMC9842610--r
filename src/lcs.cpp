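#include <Rcpp.h>
using namespace Rcpp;

// Length of the longest common subsequence of two strings.
// With match = 1, mismatch = 0, gap = 0, the score of the optimal global
// alignment (its number of identical aligned columns) equals the LCS length,
// so this is the identity numerator for the redundancy filter.
// Rolling one-row DP: O(nm) time, O(min(n,m)) memory.
// [[Rcpp::export(name = ".lcs_length")]]
int lcs_length(std::string a, std::string b) {
  if (a.size() < b.size()) std::swap(a, b);
  const int n = a.size(), m = b.size();
  if (m == 0) return 0;
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      if (ai == b[j - 1]) cur[j] = prev[j - 1] + 1;
      else cur[j] = prev[j] > cur[j - 1] ? prev[j] : cur[j - 1];
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Per-letter composition count over A, C, G, U, N (in that order); the
// clustering prefilter uses sum of pairwise minima as an exact upper bound
// on the identical-column count of any alignment.
// [[Rcpp::export(name = ".letter_counts")]]
IntegerVector letter_counts(std::string s) {
  IntegerVector out(5);
  for (size_t i = 0; i < s.size(); ++i) {
    switch (s[i]) {
      case 'A': out[0]++; break; case 'C': out[1]++; break;
      case 'G': out[2]++; break; case 'U': out[3]++; break;
      default: out[4]++;
    }
  }
  return out;
}
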