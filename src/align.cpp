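#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Gotoh global alignment with affine gaps, maximising
//   sum(substitution scores) - sum over gaps (open + ext * len).
// Deterministic traceback: diagonal > up (gap in template) > left (gap in query).
// Scores follow the ClustalW2 DNA defaults (match 1.9, mismatch 0) with the
// gap parameters exposed; 'N' scores 0 against everything including itself.

static inline double subscore(char a, char b, double match, double mismatch) {
  if (a == 'N' || b == 'N') return 0.0;
  return (a == b) ? match : mismatch;
}

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(std::string query, std::string templ,
                 double gap_open = 7.0, double gap_ext = 0.5,
                 double match = 1.9, double mismatch = 0.0) {
  const int n = (int) query.size();
  const int m = (int) templ.size();
  const double NEG = -std::numeric_limits<double>::infinity();
  // state 0 = M (a_i ~ b_j), 1 = X (gap in template, consumes query),
  // 2 = Y (gap in query, consumes template)
  std::vector<double> M((n + 1) * (m + 1), NEG), X((n + 1) * (m + 1), NEG),
      Y((n + 1) * (m + 1), NEG);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) X[at(i, 0)] = -gap_open - gap_ext * i;
  for (int j = 1; j <= m; ++j) Y[at(0, j)] = -gap_open - gap_ext * j;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = subscore(query[i - 1], templ[j - 1], match, mismatch);
      double dm = M[at(i - 1, j - 1)], dx = X[at(i - 1, j - 1)],
             dy = Y[at(i - 1, j - 1)];
      M[at(i, j)] = std::max(dm, std::max(dx, dy)) + s;
      double xm = M[at(i - 1, j)] - gap_open - gap_ext,
             xx = X[at(i - 1, j)] - gap_ext,
             xy = Y[at(i - 1, j)] - gap_open - gap_ext;
      X[at(i, j)] = std::max(xm, std::max(xx, xy));
      double ym = M[at(i, j - 1)] - gap_open - gap_ext,
             yx = X[at(i, j - 1)] - gap_open - gap_ext,
             yy = Y[at(i, j - 1)] - gap_ext;
      Y[at(i, j)] = std::max(ym, std::max(yx, yy));
    }
  }
  // traceback, preferring M, then X (up), then Y (left) on ties
  double best = M[at(n, m)];
  int state = 0;
  if (X[at(n, m)] > best) { best = X[at(n, m)]; state = 1; }
  if (Y[at(n, m)] > best) { best = Y[at(n, m)]; state = 2; }
  std::string aq, atmpl;
  int i = n, j = m;
  const double EPS = 1e-9;
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i == 0 || j == 0) stop("traceback error");
      double s = subscore(query[i - 1], templ[j - 1], match, mismatch);
      double target = M[at(i, j)] - s;
      aq.push_back(query[i - 1]);
      atmpl.push_back(templ[j - 1]);
      --i; --j;
      if (std::abs(M[at(i, j)] - target) < EPS) state = 0;
      else if (std::abs(X[at(i, j)] - target) < EPS) state = 1;
      else state = 2;
    } else if (state == 1) {
      double target;
      aq.push_back(query[i - 1]);
      atmpl.push_back('-');
      target = X[at(i, j)];
      --i;
      if (i == 0 && j == 0) break;
      if (std::abs(M[at(i, j)] - gap_open - gap_ext - target) < EPS) state = 0;
      else if (std::abs(X[at(i, j)] - gap_ext - target) < EPS) state = 1;
      else state = 2;
    } else {
      double target = Y[at(i, j)];
      aq.push_back('-');
      atmpl.push_back(templ[j - 1]);
      --j;
      if (i == 0 && j == 0) break;
      if (std::abs(M[at(i, j)] - gap_open - gap_ext - target) < EPS) state = 0;
      else if (std::abs(X[at(i, j)] - gap_open - gap_ext - target) < EPS) state = 1;
      else state = 2;
    }
  }
  std::reverse(aq.begin(), aq.end());
  std::reverse(atmpl.begin(), atmpl.end());
  return List::create(_["aligned_query"] = aq, _["aligned_template"] = atmpl,
                      _["score"] = best);
}
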