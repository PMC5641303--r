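#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Built-in deterministic folding engine primitives:
//  - nussinov_fold: maximum canonical base pairing with a minimum hairpin loop,
//    the classic Nussinov DP.
//  - duplex_fold: maximum antiparallel non-crossing canonical matching between
//    two strands (an LCS-style DP), used for stem re-prediction.
// Canonical pairs: A-U, G-C and the G-U wobble; 'N' never pairs.

static inline bool canon(char a, char b) {
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

static void nuss_traceback(int i, int j, const std::vector<int>& Mv, int n,
                           const std::string& s, int minloop,
                           IntegerVector& pt) {
  // iterative stack to avoid deep recursion
  std::vector<std::pair<int, int>> stack;
  stack.push_back({i, j});
  auto M = [&Mv, n](int a, int b) { return Mv[a * n + b]; };
  while (!stack.empty()) {
    auto [a, b] = stack.back();
    stack.pop_back();
    if (b - a < minloop + 1) continue;
    // prefer pairing (a, k) with the smallest k achieving the optimum,
    // else leave a unpaired
    bool done = false;
    for (int k = a + minloop + 1; k <= b; ++k) {
      if (!canon(s[a], s[k])) continue;
      int inner = (k - a - 1 >= minloop + 1) ? M(a + 1, k - 1) : 0;
      int right = (k + 1 <= b) ? M(k + 1, b) : 0;
      if (1 + inner + right == M(a, b)) {
        pt[a] = k + 1;  // 1-based
        pt[k] = a + 1;
        if (k - a - 1 >= minloop + 1) stack.push_back({a + 1, k - 1});
        if (k + 1 <= b) stack.push_back({k + 1, b});
        done = true;
        break;
      }
    }
    if (!done) stack.push_back({a + 1, b});
  }
}

// [[Rcpp::export(name = ".nussinov_fold")]]
IntegerVector nussinov_fold(std::string seq, int minloop = 3) {
  const int n = (int) seq.size();
  IntegerVector pt(n, 0);
  if (n == 0) return pt;
  std::vector<int> Mv(n * n, 0);
  auto M = [&Mv, n](int a, int b) -> int& { return Mv[a * n + b]; };
  for (int len = minloop + 2; len <= n; ++len) {
    for (int a = 0; a + len - 1 < n; ++a) {
      int b = a + len - 1;
      int best = M(a + 1, b);  // a unpaired
      for (int k = a + minloop + 1; k <= b; ++k) {
        if (!canon(seq[a], seq[k])) continue;
        int inner = (k - a - 1 >= minloop + 1) ? M(a + 1, k - 1) : 0;
        int right = (k + 1 <= b) ? M(k + 1, b) : 0;
        if (1 + inner + right > best) best = 1 + inner + right;
      }
      M(a, b) = best;
    }
  }
  nuss_traceback(0, n - 1, Mv, n, seq, minloop, pt);
  return pt;
}

// Maximum antiparallel matching between strand5 (5'->3') and strand3 (5'->3').
// Pairs (i, j) must be non-crossing in the duplex sense: i1 < i2 => j1 > j2.
// Returns a 2-column matrix of 1-based (pos in strand5, pos in strand3).
// [[Rcpp::export(name = ".duplex_fold")]]
IntegerMatrix duplex_fold(std::string s5, std::string s3) {
  const int n = (int) s5.size(), m = (int) s3.size();
  // align s5 against reversed s3
  std::string r3(s3.rbegin(), s3.rend());
  std::vector<int> D((n + 1) * (m + 1), 0);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j) {
      int best = std::max(D[at(i - 1, j)], D[at(i, j - 1)]);
      if (canon(s5[i - 1], r3[j - 1]))
        best = std::max(best, D[at(i - 1, j - 1)] + 1);
      D[at(i, j)] = best;
    }
  std::vector<std::pair<int, int>> pairs;
  int i = n, j = m;
  while (i > 0 && j > 0) {
    if (canon(s5[i - 1], r3[j - 1]) &&
        D[at(i, j)] == D[at(i - 1, j - 1)] + 1) {
      pairs.push_back({i, m - j + 1});  // back to original s3 coordinates
      --i; --j;
    } else if (D[at(i, j)] == D[at(i - 1, j)]) {
      --i;
    } else {
      --j;
    }
  }
  IntegerMatrix out((int) pairs.size(), 2);
  for (size_t k = 0; k < pairs.size(); ++k) {
    out(k, 0) = pairs[pairs.size() - 1 - k].first;
    out(k, 1) = pairs[pairs.size() - 1 - k].second;
  }
  return out;
}
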