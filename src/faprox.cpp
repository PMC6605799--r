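#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <functional>
using namespace Rcpp;

static const double DT_INF = 1e20;

// 1D squared-distance transform by lower envelope of parabolas
// (Felzenszwalb & Huttenlocher). f: input sampled function, d: output.
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Exact squared Euclidean distance (in pixels^2) from every pixel to the
// nearest true pixel of `mask`. Two orthogonal 1D passes; exact, O(H*W).
// [[Rcpp::export]]
NumericMatrix edt_sq_cpp(LogicalMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  int n = std::max(H, W);
  NumericMatrix g(H, W), out(H, W);
  std::vector<double> f(n), d(n), z(n + 1);
  std::vector<int> v(n);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) f[r] = mask(r, c) ? 0.0 : DT_INF;
    dt1d(f, d, v, z, H);
    for (int r = 0; r < H; ++r) g(r, c) = d[r];
  }
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) f[c] = g(r, c);
    dt1d(f, d, v, z, W);
    for (int c = 0; c < W; ++c) out(r, c) = d[c];
  }
  return out;
}

// 8-connected two-pass labeling with union-find; labels contiguous 1..n.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent(1, 0); // parent[0] unused
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a);
    b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  int next = 0;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c)) continue;
      // prior neighbors in column-major raster order:
      // (r-1, c), (r-1, c-1), (r, c-1), (r+1, c-1)
      int nb[4][2] = {{r - 1, c}, {r - 1, c - 1}, {r, c - 1}, {r + 1, c - 1}};
      int lmin = 0;
      for (int k = 0; k < 4; ++k) {
        int rr = nb[k][0], cc = nb[k][1];
        if (rr < 0 || rr >= H || cc < 0) continue;
        int l = lab(rr, cc);
        if (l > 0 && (lmin == 0 || l < lmin)) lmin = l;
      }
      if (lmin == 0) {
        ++next;
        parent.push_back(next);
        lab(r, c) = next;
      } else {
        lab(r, c) = lmin;
        for (int k = 0; k < 4; ++k) {
          int rr = nb[k][0], cc = nb[k][1];
          if (rr < 0 || rr >= H || cc < 0) continue;
          int l = lab(rr, cc);
          if (l > 0) unite(l, lmin);
        }
      }
    }
  }
  // flatten and compress to contiguous 1..n
  std::vector<int> remap(next + 1, 0);
  int n_obj = 0;
  for (int i = 1; i <= next; ++i) {
    int root = find(i);
    if (remap[root] == 0) remap[root] = ++n_obj;
    remap[i] = remap[root];
  }
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      if (lab(r, c) > 0) lab(r, c) = remap[lab(r, c)];
  lab.attr("n_objects") = n_obj;
  return lab;
}
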