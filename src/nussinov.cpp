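#include <Rcpp.h>
using namespace Rcpp;

// Maximum-weight nested folding (Nussinov-style dynamic programme).
// Canonical pair weights: GC/CG = 3, AU/UA = 2, GU/UG = 1; anything else
// (including pairs with N) is not allowed to pair. Hairpin loops must
// enclose at least min_hairpin unpaired bases, i.e. j - i > min_hairpin.
// Traceback is deterministic: at (i, j) the 5' base i is paired with the
// smallest admissible partner k that achieves the optimum; if no pairing of
// i is optimal, i is left unpaired.

static inline int pair_weight(char x, char y) {
  if ((x == 'G' && y == 'C') || (x == 'C' && y == 'G')) return 3;
  if ((x == 'A' && y == 'U') || (x == 'U' && y == 'A')) return 2;
  if ((x == 'G' && y == 'U') || (x == 'U' && y == 'G')) return 1;
  return 0;
}

// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold(std::string seq, int min_hairpin) {
  const int n = seq.size();
  std::string db(n, '.');
  if (n == 0) return List::create(_["structure"] = db, _["score"] = 0);

  // F[i][j], 0-based inclusive interval
  std::vector<std::vector<int> > F(n, std::vector<int>(n, 0));
  for (int len = min_hairpin + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = F[i + 1][j];  // i unpaired
      for (int k = i + min_hairpin + 1; k <= j; ++k) {
        int w = pair_weight(seq[i], seq[k]);
        if (!w) continue;
        int inner = F[i + 1][k - 1];
        int rest = (k + 1 <= j) ? F[k + 1][j] : 0;
        if (w + inner + rest > best) best = w + inner + rest;
      }
      F[i][j] = best;
    }
  }

  // iterative traceback
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i <= min_hairpin) continue;
    if (F[i][j] == 0) continue;
    bool paired = false;
    for (int k = i + min_hairpin + 1; k <= j; ++k) {
      int w = pair_weight(seq[i], seq[k]);
      if (!w) continue;
      int inner = F[i + 1][k - 1];
      int rest = (k + 1 <= j) ? F[k + 1][j] : 0;
      if (w + inner + rest == F[i][j]) {
        db[i] = '(';
        db[k] = ')';
        stack.push_back(std::make_pair(i + 1, k - 1));
        if (k + 1 <= j) stack.push_back(std::make_pair(k + 1, j));
        paired = true;
        break;
      }
    }
    if (!paired) stack.push_back(std::make_pair(i + 1, j));
  }

  return List::create(_["structure"] = db, _["score"] = F[0][n - 1]);
}
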