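#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 8-connected pixel-graph operations on binary masks (rows = image v axis).

// [[Rcpp::export]]
IntegerMatrix label8_cpp(IntegerMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int cr = idx % nr, cc = idx / nr;
        for (int k = 0; k < 8; ++k) {
          int rr = cr + dr[k], cr2 = cc + dc[k];
          if (rr < 0 || rr >= nr || cr2 < 0 || cr2 >= nc) continue;
          if (mask(rr, cr2) != 0 && lab(rr, cr2) == 0) {
            lab(rr, cr2) = next;
            stack.push_back(rr + cr2 * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Single-source shortest-path (geodesic) distance over the foreground of a
// mask: 8-connected, step cost 1 for axial and sqrt(2) for diagonal moves.
// Unreachable or background pixels get +Inf. Source given as 1-based (row, col).

// [[Rcpp::export]]
NumericMatrix geodesic_cpp(IntegerMatrix mask, int src_row, int src_col) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double SQ2 = std::sqrt(2.0);
  NumericMatrix dist(nr, nc);
  std::fill(dist.begin(), dist.end(), R_PosInf);
  int sr = src_row - 1, sc = src_col - 1;
  if (sr < 0 || sr >= nr || sc < 0 || sc >= nc || mask(sr, sc) == 0)
    stop("geodesic source must be a foreground pixel");
  typedef std::pair<double, int> node;
  std::priority_queue<node, std::vector<node>, std::greater<node> > pq;
  dist(sr, sc) = 0.0;
  pq.push(node(0.0, sr + sc * nr));
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const double w[8] = {SQ2, 1, SQ2, 1, 1, SQ2, 1, SQ2};
  while (!pq.empty()) {
    node top = pq.top(); pq.pop();
    int idx = top.second;
    int r = idx % nr, c = idx / nr;
    if (top.first > dist(r, c)) continue;
    for (int k = 0; k < 8; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (mask(rr, cc) == 0) continue;
      double nd = top.first + w[k];
      if (nd < dist(rr, cc)) {
        dist(rr, cc) = nd;
        pq.push(node(nd, rr + cc * nr));
      }
    }
  }
  return dist;
}
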