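// Low-level 3D voxel primitives shared by the segmentation and morphometry
// code. All arrays are column-major (R order), dims = (d1, d2, d3), index
// p = i1 + d1*(i2 + d2*i3). Spacing is carried in physical units so the
// distance transform is anisotropy-aware.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <array>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline int idx3(int i, int j, int k, int d1, int d2) {
  return i + d1 * (j + d2 * k);
}

// [[Rcpp::export(name = ".blur3d")]]
NumericVector blur3d(NumericVector v, IntegerVector dim, NumericVector sigma_vox) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  NumericVector cur = clone(v);
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma_vox[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> ker(2 * r + 1);
    double sum = 0.0;
    for (int t = -r; t <= r; ++t) {
      ker[t + r] = std::exp(-0.5 * t * t / (s * s));
      sum += ker[t + r];
    }
    for (double &k : ker) k /= sum;
    NumericVector out(cur.size());
    const int dd[3] = {d1, d2, d3};
    int n = dd[ax];
    // iterate over all lines along axis ax
    int od1 = (ax == 0) ? d2 : d1;
    int od2 = (ax == 2) ? d2 : d3;
    for (int b = 0; b < od2; ++b) {
      for (int a = 0; a < od1; ++a) {
        for (int t = 0; t < n; ++t) {
          double acc = 0.0;
          for (int u = -r; u <= r; ++u) {
            int tt = t + u;
            if (tt < 0) tt = -tt;            // reflect
            if (tt >= n) tt = 2 * n - 2 - tt;
            if (tt < 0) tt = 0;
            int p;
            if (ax == 0)      p = idx3(tt, a, b, d1, d2);
            else if (ax == 1) p = idx3(a, tt, b, d1, d2);
            else              p = idx3(a, b, tt, d1, d2);
            acc += ker[u + r] * cur[p];
          }
          int q;
          if (ax == 0)      q = idx3(t, a, b, d1, d2);
          else if (ax == 1) q = idx3(a, t, b, d1, d2);
          else              q = idx3(a, b, t, d1, d2);
          out[q] = acc;
        }
      }
    }
    cur = out;
  }
  return cur;
}

// 26-connected component labelling, labels assigned in scan order.
// [[Rcpp::export(name = ".label3d")]]
IntegerVector label3d(IntegerVector fg, IntegerVector dim) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const int n = d1 * d2 * d3;
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (int p0 = 0; p0 < n; ++p0) {
    if (fg[p0] == 0 || lab[p0] != 0) continue;
    ++next;
    lab[p0] = next;
    stack.push_back(p0);
    while (!stack.empty()) {
      int p = stack.back();
      stack.pop_back();
      int k = p / (d1 * d2);
      int rem = p - k * d1 * d2;
      int j = rem / d1;
      int i = rem - j * d1;
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3) continue;
            int q = idx3(ii, jj, kk, d1, d2);
            if (fg[q] != 0 && lab[q] == 0) {
              lab[q] = next;
              stack.push_back(q);
            }
          }
    }
  }
  lab.attr("n_labels") = next;
  return lab;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher), sample step s.
static void dt1d(const std::vector<double> &f, std::vector<double> &dout,
                 int n, double s) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  const double s2 = s * s;
  for (int q = 1; q < n; ++q) {
    double sx;
    while (true) {
      int p = v[k];
      sx = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) / (2.0 * s2 * (q - p));
      if (sx <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = sx;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)(q - v[k]);
    dout[q] = s2 * dq * dq + f[v[k]];
  }
}

// Anisotropic Euclidean distance transform: distance (physical units) from
// each foreground voxel to the nearest background voxel.
// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(IntegerVector fg, IntegerVector dim, NumericVector spacing) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const int n = d1 * d2 * d3;
  const double BIG = 1e30;
  NumericVector d(n);
  for (int p = 0; p < n; ++p) d[p] = fg[p] != 0 ? BIG : 0.0;
  const int dd[3] = {d1, d2, d3};
  for (int ax = 0; ax < 3; ++ax) {
    int m = dd[ax];
    if (m == 1) continue;
    std::vector<double> f(m), g(m);
    int od1 = (ax == 0) ? d2 : d1;
    int od2 = (ax == 2) ? d2 : d3;
    for (int b = 0; b < od2; ++b)
      for (int a = 0; a < od1; ++a) {
        for (int t = 0; t < m; ++t) {
          int p = (ax == 0) ? idx3(t, a, b, d1, d2)
                : (ax == 1) ? idx3(a, t, b, d1, d2)
                            : idx3(a, b, t, d1, d2);
          f[t] = d[p];
        }
        dt1d(f, g, m, spacing[ax]);
        for (int t = 0; t < m; ++t) {
          int p = (ax == 0) ? idx3(t, a, b, d1, d2)
                : (ax == 1) ? idx3(a, t, b, d1, d2)
                            : idx3(a, b, t, d1, d2);
          d[p] = g[t];
        }
      }
  }
  for (int p = 0; p < n; ++p) d[p] = std::sqrt(d[p]);
  return d;
}

// Greyscale reconstruction by dilation (marker <= mask), 26-connectivity.
// Hybrid algorithm: forward/backward raster scans then FIFO propagation.
// [[Rcpp::export(name = ".reconstruct3d")]]
NumericVector reconstruct3d(NumericVector marker, NumericVector mask,
                            IntegerVector dim) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const int n = d1 * d2 * d3;
  NumericVector J = clone(marker);
  for (int p = 0; p < n; ++p) if (J[p] > mask[p]) J[p] = mask[p];
  // neighbour offsets split into "already visited" (forward) halves
  std::vector<std::array<int,3>> nb;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di)
        if (di || dj || dk) nb.push_back({di, dj, dk});
  auto is_forward = [](const std::array<int,3> &o) {
    if (o[2] != 0) return o[2] < 0;
    if (o[1] != 0) return o[1] < 0;
    return o[0] < 0;
  };
  // forward scan
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        int p = idx3(i, j, k, d1, d2);
        double m = J[p];
        for (auto &o : nb) {
          if (!is_forward(o)) continue;
          int ii = i + o[0], jj = j + o[1], kk = k + o[2];
          if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3) continue;
          double val = J[idx3(ii, jj, kk, d1, d2)];
          if (val > m) m = val;
        }
        J[p] = std::min(m, mask[p]);
      }
  // backward scan + queue init
  std::queue<int> fifo;
  for (int k = d3 - 1; k >= 0; --k)
    for (int j = d2 - 1; j >= 0; --j)
      for (int i = d1 - 1; i >= 0; --i) {
        int p = idx3(i, j, k, d1, d2);
        double m = J[p];
        for (auto &o : nb) {
          if (is_forward(o)) continue;
          int ii = i + o[0], jj = j + o[1], kk = k + o[2];
          if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3) continue;
          double val = J[idx3(ii, jj, kk, d1, d2)];
          if (val > m) m = val;
        }
        J[p] = std::min(m, mask[p]);
        for (auto &o : nb) {
          if (is_forward(o)) continue;
          int ii = i + o[0], jj = j + o[1], kk = k + o[2];
          if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3) continue;
          int q = idx3(ii, jj, kk, d1, d2);
          if (J[q] < J[p] && J[q] < mask[q]) { fifo.push(p); break; }
        }
      }
  // propagation
  while (!fifo.empty()) {
    int p = fifo.front();
    fifo.pop();
    int k = p / (d1 * d2);
    int rem = p - k * d1 * d2;
    int j = rem / d1;
    int i = rem - j * d1;
    for (auto &o : nb) {
      int ii = i + o[0], jj = j + o[1], kk = k + o[2];
      if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3) continue;
      int q = idx3(ii, jj, kk, d1, d2);
      if (J[q] < J[p] && mask[q] != J[q]) {
        J[q] = std::min(J[p], mask[q]);
        fifo.push(q);
      }
    }
  }
  return J;
}

struct WsNode {
  double prio;
  long order;
  int idx;
};
struct WsCmp {
  bool operator()(const WsNode &a, const WsNode &b) const {
    if (a.prio != b.prio) return a.prio < b.prio;  // max-heap on priority
    return a.order > b.order;                      // FIFO on ties
  }
};

// Seeded watershed: flood the domain from labelled seeds in order of
// decreasing priority (pass the distance map as priority to split touching
// convex objects). Deterministic: ties broken by insertion order.
// [[Rcpp::export(name = ".watershed3d")]]
IntegerVector watershed3d(NumericVector priority, IntegerVector seeds,
                          IntegerVector domain, IntegerVector dim) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const int n = d1 * d2 * d3;
  IntegerVector lab = clone(seeds);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long counter = 0;
  for (int p = 0; p < n; ++p)
    if (lab[p] > 0 && domain[p] != 0) pq.push({priority[p], counter++, p});
  while (!pq.empty()) {
    WsNode nd = pq.top();
    pq.pop();
    int p = nd.idx;
    int k = p / (d1 * d2);
    int rem = p - k * d1 * d2;
    int j = rem / d1;
    int i = rem - j * d1;
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0 && dk == 0) continue;
          int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3) continue;
          int q = idx3(ii, jj, kk, d1, d2);
          if (domain[q] != 0 && lab[q] == 0) {
            lab[q] = lab[p];
            pq.push({priority[q], counter++, q});
          }
        }
  }
  return lab;
}

// Foreground voxels with a 6-neighbour background (or image border) contact.
// [[Rcpp::export(name = ".boundary6")]]
IntegerVector boundary6(IntegerVector fg, IntegerVector dim) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const int n = d1 * d2 * d3;
  IntegerVector out(n, 0);
  const int off[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        int p = idx3(i, j, k, d1, d2);
        if (fg[p] == 0) continue;
        bool bd = false;
        for (int t = 0; t < 6 && !bd; ++t) {
          int ii = i + off[t][0], jj = j + off[t][1], kk = k + off[t][2];
          if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3) bd = true;
          else if (fg[idx3(ii, jj, kk, d1, d2)] == 0) bd = true;
        }
        if (bd) out[p] = 1;
      }
  return out;
}

// Symmetric grey-level co-occurrence counts over the given voxel offsets.
// levels: 1..G inside the object, 0 outside; pairs need both ends inside.
// [[Rcpp::export(name = ".glcm_accum")]]
NumericMatrix glcm_accum(IntegerVector levels, IntegerVector dim, int G,
                         IntegerMatrix offsets) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  NumericMatrix M(G, G);
  for (int r = 0; r < offsets.nrow(); ++r) {
    int o1 = offsets(r, 0), o2 = offsets(r, 1), o3 = offsets(r, 2);
    for (int k = 0; k < d3; ++k)
      for (int j = 0; j < d2; ++j)
        for (int i = 0; i < d1; ++i) {
          int p = idx3(i, j, k, d1, d2);
          if (levels[p] == 0) continue;
          int ii = i + o1, jj = j + o2, kk = k + o3;
          if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3) continue;
          int q = idx3(ii, jj, kk, d1, d2);
          if (levels[q] == 0) continue;
          M(levels[p] - 1, levels[q] - 1) += 1.0;
          M(levels[q] - 1, levels[p] - 1) += 1.0;  // symmetric
        }
  }
  return M;
}
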