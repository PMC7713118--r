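#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// 0-dimensional sublevel-set persistence of a scalar field on the pixel
// grid, by union-find with path compression and union by rank.
//
// Pixels are processed in increasing (value, row, col) order; a component is
// born at its minimum pixel and, when two components meet at pixel p, the
// one whose minimum has the larger (value, row, col) key dies there (elder
// rule, deterministic lexicographic tie-break).
//
// With virtual_border = true an extra node valued -Inf adjacent to every
// border pixel is processed first; its component is flagged in the output.
// This is the engine behind both H0 (8-connectivity) and, on the negated
// image with 4-connectivity, the dual computation of H1.

namespace {

struct UF {
  std::vector<int> parent, rank_, birth; // birth: pixel id of component min
  explicit UF(int n) : parent(n), rank_(n, 0), birth(n, -1) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    int root = x;
    while (parent[root] != root) root = parent[root];
    while (parent[x] != root) { int nxt = parent[x]; parent[x] = root; x = nxt; }
    return root;
  }
  int unite(int a, int b, int elder_birth) {
    if (rank_[a] < rank_[b]) std::swap(a, b);
    parent[b] = a;
    if (rank_[a] == rank_[b]) ++rank_[a];
    birth[a] = elder_birth;
    return a;
  }
};

} // namespace

// [[Rcpp::export(name = ".ph0_cpp")]]
List ph0_cpp(NumericMatrix img, int connectivity, bool virtual_border) {
  const int H = img.nrow(), W = img.ncol(), n = H * W;
  const int VIRT = n; // id of the virtual border node
  const int ntot = virtual_border ? n + 1 : n;

  // processing order: (value, row, col) ascending; virtual node first
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  const double *v = img.begin(); // column-major: id = c*H + r
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (v[a] != v[b]) return v[a] < v[b];
    int ra = a % H, ca = a / H, rb = b % H, cb = b / H;
    if (ra != rb) return ra < rb;
    return ca < cb;
  });

  // birth key comparison: virtual node is elder to everything
  auto elder_of = [&](int pa, int pb) {
    // returns true if birth pixel pa is elder (smaller key) than pb
    if (pa == VIRT) return true;
    if (pb == VIRT) return false;
    if (v[pa] != v[pb]) return v[pa] < v[pb];
    int ra = pa % H, ca = pa / H, rb = pb % H, cb = pb / H;
    if (ra != rb) return ra < rb;
    return ca < cb;
  };

  UF uf(ntot);
  std::vector<char> active(ntot, 0);
  if (virtual_border) { active[VIRT] = 1; uf.birth[VIRT] = VIRT; }

  std::vector<double> births, deaths;
  std::vector<int> b_pix, d_pix;

  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 1, 0, 0};
  const int dc4[4] = {0, 0, -1, 1};
  const int *dr = (connectivity == 8) ? dr8 : dr4;
  const int *dc = (connectivity == 8) ? dc8 : dc4;
  const int nn = (connectivity == 8) ? 8 : 4;

  for (int idx = 0; idx < n; ++idx) {
    int p = ord[idx];
    int r = p % H, c = p / H;
    active[p] = 1;
    uf.birth[p] = p;
    for (int k = 0; k <= nn; ++k) {
      int q;
      if (k < nn) {
        int rq = r + dr[k], cq = c + dc[k];
        if (rq < 0 || rq >= H || cq < 0 || cq >= W) continue;
        q = cq * H + rq;
        if (!active[q]) continue;
      } else {
        if (!virtual_border) continue;
        if (r != 0 && r != H - 1 && c != 0 && c != W - 1) continue;
        q = VIRT;
      }
      int rp = uf.find(p), rq2 = uf.find(q);
      if (rp == rq2) continue;
      int bp = uf.birth[rp], bq = uf.birth[rq2];
      bool p_elder = elder_of(bp, bq);
      int young_birth = p_elder ? bq : bp;
      int elder_birth = p_elder ? bp : bq;
      if (young_birth != p) {
        // a real component dies; p joining an older component (its own
        // singleton just created here) is not a local minimum and leaves
        // no diagram point
        births.push_back(v[young_birth]);
        deaths.push_back(v[p]);
        b_pix.push_back(young_birth);
        d_pix.push_back(p);
      }
      uf.unite(rp, rq2, elder_birth);
    }
  }

  // surviving components: infinite points
  std::vector<char> seen(ntot, 0);
  std::vector<int> inf_birth;
  std::vector<char> inf_virtual;
  for (int i = 0; i < ntot; ++i) {
    if (!active[i]) continue;
    int root = uf.find(i);
    if (seen[root]) continue;
    seen[root] = 1;
    inf_birth.push_back(uf.birth[root]);
    inf_virtual.push_back(uf.birth[root] == VIRT ? 1 : 0);
  }

  const int nf = (int)births.size(), ni = (int)inf_birth.size();
  NumericVector birth(nf + ni), death(nf + ni);
  IntegerVector br(nf + ni), bc(nf + ni), dr_(nf + ni), dc_(nf + ni);
  LogicalVector is_virtual(nf + ni);
  for (int i = 0; i < nf; ++i) {
    birth[i] = births[i];
    death[i] = deaths[i];
    br[i] = b_pix[i] % H + 1;
    bc[i] = b_pix[i] / H + 1;
    dr_[i] = d_pix[i] % H + 1;
    dc_[i] = d_pix[i] / H + 1;
    is_virtual[i] = false;
  }
  for (int i = 0; i < ni; ++i) {
    int j = nf + i;
    death[j] = R_PosInf;
    dr_[j] = NA_INTEGER;
    dc_[j] = NA_INTEGER;
    if (inf_virtual[i]) {
      birth[j] = R_NegInf;
      br[j] = NA_INTEGER;
      bc[j] = NA_INTEGER;
      is_virtual[j] = true;
    } else {
      birth[j] = v[inf_birth[i]];
      br[j] = inf_birth[i] % H + 1;
      bc[j] = inf_birth[i] / H + 1;
      is_virtual[j] = false;
    }
  }
  return List::create(_["birth"] = birth, _["death"] = death,
                      _["birth_row"] = br, _["birth_col"] = bc,
                      _["death_row"] = dr_, _["death_col"] = dc_,
                      _["virtual"] = is_virtual);
}
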