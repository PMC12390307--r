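#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Breadth-first region growing on the pixel grid (4-connectivity).
// A pixel joins the region if its eligibility flag is set and its depth is
// continuous with the accepted neighbour it is reached from (|delta| <=
// depth_tol); edges where either depth is missing are not blocked — the
// eligibility mask is the gate there.
// [[Rcpp::export(name = ".flood_fill_cpp")]]
LogicalMatrix flood_fill_cpp(LogicalMatrix eligible, NumericMatrix depth,
                             int seed_row, int seed_col, double depth_tol) {
  int H = eligible.nrow(), W = eligible.ncol();
  LogicalMatrix out(H, W);
  if (seed_row < 1 || seed_row > H || seed_col < 1 || seed_col > W)
    stop("seed outside image");
  int sr = seed_row - 1, sc = seed_col - 1;
  if (!eligible(sr, sc)) return out;
  std::queue<std::pair<int, int> > q;
  out(sr, sc) = true;
  q.push(std::make_pair(sr, sc));
  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};
  while (!q.empty()) {
    std::pair<int, int> cur = q.front();
    q.pop();
    double d0 = depth(cur.first, cur.second);
    for (int k = 0; k < 4; ++k) {
      int r = cur.first + dr[k], c = cur.second + dc[k];
      if (r < 0 || r >= H || c < 0 || c >= W) continue;
      if (out(r, c) || !eligible(r, c)) continue;
      double d1 = depth(r, c);
      if (R_finite(d0) && R_finite(d1) && fabs(d1 - d0) > depth_tol) continue;
      out(r, c) = true;
      q.push(std::make_pair(r, c));
    }
  }
  return out;
}
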