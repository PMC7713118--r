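#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Grid utilities: flood fill of a connected component and an exact
// Euclidean distance transform that also reports the nearest site
// (Felzenszwalb-Huttenlocher lower-envelope scheme, per row after a
// per-column sweep), used by the inverse-distance-weighted fill.

// [[Rcpp::export(name = ".flood_fill_cpp")]]
LogicalMatrix flood_fill_cpp(LogicalMatrix mask, int r0, int c0,
                             int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  LogicalMatrix out(H, W);
  if (r0 < 1 || r0 > H || c0 < 1 || c0 > W) stop("seed outside image");
  if (!mask(r0 - 1, c0 - 1)) return out;
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 1, 0, 0};
  const int dc4[4] = {0, 0, -1, 1};
  const int *dr = (connectivity == 8) ? dr8 : dr4;
  const int *dc = (connectivity == 8) ? dc8 : dc4;
  const int nn = (connectivity == 8) ? 8 : 4;
  std::vector<int> stack;
  stack.push_back((c0 - 1) * H + (r0 - 1));
  out(r0 - 1, c0 - 1) = true;
  while (!stack.empty()) {
    int p = stack.back();
    stack.pop_back();
    int r = p % H, c = p / H;
    for (int k = 0; k < nn; ++k) {
      int rq = r + dr[k], cq = c + dc[k];
      if (rq < 0 || rq >= H || cq < 0 || cq >= W) continue;
      if (mask(rq, cq) && !out(rq, cq)) {
        out(rq, cq) = true;
        stack.push_back(cq * H + rq);
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".nearest_site_cpp")]]
List nearest_site_cpp(LogicalMatrix sites) {
  const int H = sites.nrow(), W = sites.ncol();
  const double INF = 1e30;
  // pass 1: nearest site within each column
  std::vector<double> d1(H * W, INF);
  std::vector<int> row1(H * W, -1);
  for (int c = 0; c < W; ++c) {
    int last = -1;
    for (int r = 0; r < H; ++r) {
      if (sites(r, c)) last = r;
      if (last >= 0) { d1[c * H + r] = r - last; row1[c * H + r] = last; }
    }
    last = -1;
    for (int r = H - 1; r >= 0; --r) {
      if (sites(r, c)) last = r;
      if (last >= 0 && last - r < d1[c * H + r]) {
        d1[c * H + r] = last - r;
        row1[c * H + r] = last;
      }
    }
  }
  // pass 2: 1-d squared-distance transform along each row
  NumericMatrix dist(H, W);
  IntegerMatrix nr(H, W), nc(H, W);
  std::vector<int> vx(W);
  std::vector<double> z(W + 1), f(W);
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      double d = d1[c * H + r];
      f[c] = (d >= INF) ? INF : d * d;
    }
    int k = 0;
    vx[0] = 0;
    z[0] = -INF;
    z[1] = INF;
    for (int q = 1; q < W; ++q) {
      if (f[q] >= INF) continue;
      double s;
      while (true) {
        int p = vx[k];
        if (f[p] >= INF) { // degenerate leading parabola
          s = -INF;
        } else {
          s = ((f[q] + (double)q * q) - (f[p] + (double)p * p)) /
              (2.0 * q - 2.0 * p);
        }
        if (s <= z[k]) {
          if (k == 0) { vx[0] = q; z[0] = -INF; z[1] = INF; s = NA_REAL; break; }
          --k;
        } else {
          ++k;
          vx[k] = q;
          z[k] = s;
          z[k + 1] = INF;
          break;
        }
      }
    }
    int kk = 0;
    for (int q = 0; q < W; ++q) {
      while (z[kk + 1] < q) ++kk;
      int p = vx[kk];
      if (f[p] >= INF) {
        dist(r, q) = NA_REAL;
        nr(r, q) = NA_INTEGER;
        nc(r, q) = NA_INTEGER;
      } else {
        double dd = (double)(q - p) * (q - p) + f[p];
        dist(r, q) = std::sqrt(dd);
        nr(r, q) = row1[p * H + r] + 1;
        nc(r, q) = p + 1;
      }
    }
  }
  return List::create(_["dist"] = dist, _["nearest_row"] = nr,
                      _["nearest_col"] = nc);
}
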