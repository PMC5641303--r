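#include <Rcpp.h>
#include <vector>
#include <functional>
#include <algorithm>
using namespace Rcpp;

// Ordered-tree edit distance between RNA structure trees (Zhang-Shasha, unit
// costs). The tree is the full representation: a virtual root, one internal
// node per base pair (label P) and one leaf per unpaired position (label U),
// children ordered 5'->3'.

namespace {

struct Tree {
  std::vector<int> label;  // postorder, 1-based slots at [1..T]; 0=R,1=P,2=U
  std::vector<int> lml;    // leftmost leaf descendant, postorder index
  int T = 0;
};

// pt: 1-based pair table (0 = unpaired), assumed nested
Tree build_tree(const IntegerVector& pt) {
  const int n = pt.size();
  Tree tr;
  tr.label.push_back(0);  // dummy at index 0
  tr.lml.push_back(0);
  std::function<int(int, int, int)> emit =
      // emits all nodes for interval [i..j] (children of one parent), returns
      // postorder index of the first leaf emitted in the subtree rooted at the
      // parent, or 0 if none; parent emitted by caller
      [&](int i, int j, int dummy) -> int { return 0; };
  // recursive: process interval, return postorder index of leftmost leaf
  std::function<int(int, int)> walk = [&](int i, int j) -> int {
    int first = 0;
    int p = i;
    while (p <= j) {
      if (pt[p - 1] == 0) {
        tr.label.push_back(2);
        tr.T++;
        tr.lml.push_back(tr.T);
        if (!first) first = tr.T;
        ++p;
      } else {
        int q = pt[p - 1];
        int sub_first = walk(p + 1, q - 1);
        tr.label.push_back(1);
        tr.T++;
        tr.lml.push_back(sub_first ? sub_first : tr.T);
        if (!first) first = (sub_first ? sub_first : tr.T);
        p = q + 1;
      }
    }
    return first;
  };
  int sub_first = walk(1, n);
  tr.label.push_back(0);  // virtual root
  tr.T++;
  tr.lml.push_back(sub_first ? sub_first : tr.T);
  return tr;
}

int zss(const Tree& a, const Tree& b) {
  const int T1 = a.T, T2 = b.T;
  // keyroots: highest node for each distinct lml value
  std::vector<int> kr1, kr2;
  {
    std::vector<int> seen(T1 + 1, 0);
    for (int i = T1; i >= 1; --i)
      if (!seen[a.lml[i]]) { seen[a.lml[i]] = 1; kr1.push_back(i); }
    std::sort(kr1.begin(), kr1.end());
    std::vector<int> seen2(T2 + 1, 0);
    for (int j = T2; j >= 1; --j)
      if (!seen2[b.lml[j]]) { seen2[b.lml[j]] = 1; kr2.push_back(j); }
    std::sort(kr2.begin(), kr2.end());
  }
  std::vector<int> TD((T1 + 1) * (T2 + 1), 0);
  auto td = [&TD, T2](int i, int j) -> int& { return TD[i * (T2 + 1) + j]; };
  std::vector<int> fd;
  for (int k1 : kr1) {
    int l1 = a.lml[k1];
    int rows = k1 - l1 + 2;
    for (int k2 : kr2) {
      int l2 = b.lml[k2];
      int cols = k2 - l2 + 2;
      fd.assign(rows * cols, 0);
      auto f = [&fd, cols](int r, int c) -> int& { return fd[r * cols + c]; };
      for (int r = 1; r < rows; ++r) f(r, 0) = f(r - 1, 0) + 1;
      for (int c = 1; c < cols; ++c) f(0, c) = f(0, c - 1) + 1;
      for (int i = l1; i <= k1; ++i) {
        int r = i - l1 + 1;
        for (int j = l2; j <= k2; ++j) {
          int c = j - l2 + 1;
          if (a.lml[i] == l1 && b.lml[j] == l2) {
            int ren = (a.label[i] == b.label[j]) ? 0 : 1;
            int v = std::min(std::min(f(r - 1, c) + 1, f(r, c - 1) + 1),
                             f(r - 1, c - 1) + ren);
            f(r, c) = v;
            td(i, j) = v;
          } else {
            int pr = a.lml[i] - l1;      // row index of forest left of subtree i
            int pc = b.lml[j] - l2;
            int v = std::min(std::min(f(r - 1, c) + 1, f(r, c - 1) + 1),
                             f(pr, pc) + td(i, j));
            f(r, c) = v;
          }
        }
      }
    }
  }
  return td(T1, T2);
}

}  // namespace

// [[Rcpp::export(name = ".tree_edit_distance_pt")]]
int tree_edit_distance_pt(IntegerVector pt1, IntegerVector pt2) {
  Tree a = build_tree(pt1);
  Tree b = build_tree(pt2);
  return zss(a, b);
}

// Postorder labels of the structure tree (0 = root, 1 = pair, 2 = unpaired),
// with leftmost-leaf indices; used by tests to check tree shape.
// [[Rcpp::export(name = ".structure_tree_postorder")]]
List structure_tree_postorder(IntegerVector pt) {
  Tree a = build_tree(pt);
  IntegerVector lab(a.T), lml(a.T);
  for (int i = 1; i <= a.T; ++i) { lab[i - 1] = a.label[i]; lml[i - 1] = a.lml[i]; }
  return List::create(_["label"] = lab, _["lml"] = lml);
}
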