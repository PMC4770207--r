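#include <Rcpp.h>
#include <set>
using namespace Rcpp;

// Maximum base-pairing (Nussinov-style) secondary structure prediction.
// Used by the deterministic mock folding backend. Pairs: Watson-Crick + GU.
// Coordinates are 1-based in the returned pair table; 0 = unpaired.

static inline bool wc_or_wobble(char a, char b) {
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// [[Rcpp::export(name = ".nussinov_pairs")]]
IntegerVector nussinov_pairs_cpp(std::string seq, int min_loop = 3,
                                 Nullable<IntegerMatrix> banned_pairs = R_NilValue,
                                 Nullable<IntegerVector> banned_pos = R_NilValue) {
  const int n = (int) seq.size();
  IntegerVector pt(n, 0);
  if (n < 2) return pt;

  std::set<std::pair<int,int> > banned;
  if (banned_pairs.isNotNull()) {
    IntegerMatrix bp(banned_pairs);
    for (int r = 0; r < bp.nrow(); ++r) {
      int i = bp(r, 0), j = bp(r, 1);
      if (i > j) std::swap(i, j);
      banned.insert(std::make_pair(i, j));
    }
  }
  std::vector<bool> posban(n + 1, false);
  if (banned_pos.isNotNull()) {
    IntegerVector bv(banned_pos);
    for (int r = 0; r < bv.size(); ++r)
      if (bv[r] >= 1 && bv[r] <= n) posban[bv[r]] = true;
  }

  // allowed(i, j), 1-based
  auto allowed = [&](int i, int j) -> bool {
    if (j - i <= min_loop) return false;
    if (posban[i] || posban[j]) return false;
    if (!wc_or_wobble(seq[i - 1], seq[j - 1])) return false;
    if (!banned.empty() &&
        banned.count(std::make_pair(i, j))) return false;
    return true;
  };

  // DP over 0-based half matrix: N[i][j] = max pairs in seq[i..j]
  std::vector< std::vector<short> > N(n, std::vector<short>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      short best = N[i][j - 1];              // j unpaired
      for (int k = i; k <= j - min_loop - 1; ++k) {  // j pairs with k
        if (!allowed(k + 1, j + 1)) continue;
        short v = (short) (1 + (k > i ? N[i][k - 1] : 0) +
                           (k + 1 <= j - 1 ? N[k + 1][j - 1] : 0));
        if (v > best) best = v;
      }
      N[i][j] = best;
    }
  }

  // deterministic traceback (smallest k preferred)
  std::vector< std::pair<int,int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i < min_loop + 1) continue;
    if (N[i][j] == N[i][j - 1]) {
      stack.push_back(std::make_pair(i, j - 1));
      continue;
    }
    for (int k = i; k <= j - min_loop - 1; ++k) {
      if (!allowed(k + 1, j + 1)) continue;
      short v = (short) (1 + (k > i ? N[i][k - 1] : 0) +
                         (k + 1 <= j - 1 ? N[k + 1][j - 1] : 0));
      if (v == N[i][j]) {
        pt[k] = j + 1;
        pt[j] = k + 1;
        if (k > i) stack.push_back(std::make_pair(i, k - 1));
        if (k + 1 <= j - 1) stack.push_back(std::make_pair(k + 1, j - 1));
        break;
      }
    }
  }
  return pt;
}
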