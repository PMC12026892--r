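// 3D image-processing primitives on column-major (x, y, z) arrays.
// Footprints are passed as integer voxel offsets so callers can express
// them in physical units on anisotropic grids.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// type: 0 = min (erosion), 1 = max (dilation), 2 = median.
// Out-of-bounds neighbours are clamped to the nearest edge voxel.
// [[Rcpp::export]]
NumericVector cpp_rank_filter(NumericVector arr, IntegerVector dim,
                              IntegerMatrix offsets, int type) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int noff = offsets.nrow();
  NumericVector out(arr.size());
  std::vector<double> buf(noff);
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        for (int k = 0; k < noff; ++k) {
          int xx = clampi(x + offsets(k, 0), 0, nx - 1);
          int yy = clampi(y + offsets(k, 1), 0, ny - 1);
          int zz = clampi(z + offsets(k, 2), 0, nz - 1);
          buf[k] = arr[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
        }
        double v;
        if (type == 0) {
          v = *std::min_element(buf.begin(), buf.end());
        } else if (type == 1) {
          v = *std::max_element(buf.begin(), buf.end());
        } else {
          std::vector<double> tmp(buf);
          size_t mid = tmp.size() / 2;
          std::nth_element(tmp.begin(), tmp.begin() + mid, tmp.end());
          if (tmp.size() % 2 == 1) {
            v = tmp[mid];
          } else {
            double hi = tmp[mid];
            double lo = *std::max_element(tmp.begin(), tmp.begin() + mid);
            v = 0.5 * (lo + hi);
          }
        }
        out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = v;
      }
    }
  }
  return out;
}

// 1D convolution along one axis (0 = x, 1 = y, 2 = z) with edge replication.
// kernel has odd length; its centre aligns with the output voxel.
// [[Rcpp::export]]
NumericVector cpp_convolve_axis(NumericVector arr, IntegerVector dim,
                                NumericVector kernel, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int kr = (kernel.size() - 1) / 2;
  NumericVector out(arr.size());
  const int n[3] = {nx, ny, nz};
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        double acc = 0.0;
        int c[3] = {x, y, z};
        for (int k = -kr; k <= kr; ++k) {
          int cc[3] = {x, y, z};
          cc[axis] = clampi(c[axis] + k, 0, n[axis] - 1);
          acc += kernel[k + kr] *
                 arr[cc[0] + (R_xlen_t)nx * (cc[1] + (R_xlen_t)ny * cc[2])];
        }
        out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = acc;
      }
    }
  }
  return out;
}

static const int NB6[6][3] = {{1, 0, 0},  {-1, 0, 0}, {0, 1, 0},
                              {0, -1, 0}, {0, 0, 1},  {0, 0, -1}};

// Grayscale morphological reconstruction by dilation (6-connectivity):
// iteratively dilate `seed` under `mask` until stable. Hybrid
// raster-scan + FIFO algorithm, so it converges in two sweeps plus a
// queue drain regardless of image content.
// [[Rcpp::export]]
NumericVector cpp_reconstruct_dilation(NumericVector seed, NumericVector mask,
                                       IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector J = clone(seed);
  const R_xlen_t N = J.size();
  for (R_xlen_t i = 0; i < N; ++i)
    if (J[i] > mask[i]) J[i] = mask[i];

  // forward raster: neighbours already visited (dx|dy|dz negative side)
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        double m = J[i];
        if (x > 0) m = std::max(m, J[i - 1]);
        if (y > 0) m = std::max(m, J[i - nx]);
        if (z > 0) m = std::max(m, J[i - (R_xlen_t)nx * ny]);
        J[i] = std::min(m, mask[i]);
      }
  // backward raster + queue seeding
  std::queue<R_xlen_t> fifo;
  for (int z = nz - 1; z >= 0; --z)
    for (int y = ny - 1; y >= 0; --y)
      for (int x = nx - 1; x >= 0; --x) {
        R_xlen_t i = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        double m = J[i];
        if (x < nx - 1) m = std::max(m, J[i + 1]);
        if (y < ny - 1) m = std::max(m, J[i + nx]);
        if (z < nz - 1) m = std::max(m, J[i + (R_xlen_t)nx * ny]);
        J[i] = std::min(m, mask[i]);
        // queue if some scanned neighbour could still grow
        bool push = false;
        if (x < nx - 1 && J[i + 1] < J[i] && J[i + 1] < mask[i + 1]) push = true;
        if (!push && y < ny - 1 && J[i + nx] < J[i] && J[i + nx] < mask[i + nx])
          push = true;
        if (!push && z < nz - 1) {
          R_xlen_t j = i + (R_xlen_t)nx * ny;
          if (J[j] < J[i] && J[j] < mask[j]) push = true;
        }
        if (push) fifo.push(i);
      }
  while (!fifo.empty()) {
    R_xlen_t i = fifo.front();
    fifo.pop();
    int z = (int)(i / ((R_xlen_t)nx * ny));
    int rem = (int)(i % ((R_xlen_t)nx * ny));
    int y = rem / nx, x = rem % nx;
    for (int k = 0; k < 6; ++k) {
      int xx = x + NB6[k][0], yy = y + NB6[k][1], zz = z + NB6[k][2];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
        continue;
      R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
      if (J[j] < J[i] && mask[j] != J[j]) {
        J[j] = std::min(J[i], mask[j]);
        fifo.push(j);
      }
    }
  }
  return J;
}

// Connected-component labelling of a logical mask.
// connectivity: 6 or 26. Labels assigned in raster-scan discovery order.
// [[Rcpp::export]]
IntegerVector cpp_label(LogicalVector mask, IntegerVector dim,
                        int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector lab(mask.size(), 0);
  std::vector<std::array<int, 3>> nbs;
  if (connectivity == 6) {
    for (int k = 0; k < 6; ++k)
      nbs.push_back({NB6[k][0], NB6[k][1], NB6[k][2]});
  } else {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          if (dx || dy || dz) nbs.push_back({dx, dy, dz});
  }
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t i = 0; i < mask.size(); ++i) {
    if (!mask[i] || lab[i]) continue;
    lab[i] = ++next;
    q.push(i);
    while (!q.empty()) {
      R_xlen_t c = q.front();
      q.pop();
      int z = (int)(c / ((R_xlen_t)nx * ny));
      int rem = (int)(c % ((R_xlen_t)nx * ny));
      int y = rem / nx, x = rem % nx;
      for (auto &d : nbs) {
        int xx = x + d[0], yy = y + d[1], zz = z + d[2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[j] && !lab[j]) {
          lab[j] = next;
          q.push(j);
        }
      }
    }
  }
  lab.attr("max") = next;
  return lab;
}

struct WsNode {
  double prio;
  R_xlen_t ord;
  R_xlen_t idx;
  int label;
};
struct WsCmp {
  bool operator()(const WsNode &a, const WsNode &b) const {
    if (a.prio != b.prio) return a.prio > b.prio;  // lower priority first
    return a.ord > b.ord;                          // FIFO tie-break
  }
};

// Marker-controlled watershed: flood `priority` (ascending) from labelled
// markers, restricted to `mask`. 6-connectivity; deterministic FIFO
// tie-breaking. Returns a label volume.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector priority, IntegerVector markers,
                            LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector lab = clone(markers);
  std::vector<char> queued(lab.size(), 0);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  R_xlen_t ord = 0;
  auto expand = [&](R_xlen_t i, int label) {
    int z = (int)(i / ((R_xlen_t)nx * ny));
    int rem = (int)(i % ((R_xlen_t)nx * ny));
    int y = rem / nx, x = rem % nx;
    for (int k = 0; k < 6; ++k) {
      int xx = x + NB6[k][0], yy = y + NB6[k][1], zz = z + NB6[k][2];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
        continue;
      R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
      if (mask[j] && lab[j] == 0 && !queued[j]) {
        queued[j] = 1;
        pq.push({priority[j], ord++, j, label});
      }
    }
  };
  for (R_xlen_t i = 0; i < lab.size(); ++i)
    if (lab[i] > 0 && !mask[i]) lab[i] = 0;
  for (R_xlen_t i = 0; i < lab.size(); ++i)
    if (lab[i] > 0) expand(i, lab[i]);
  while (!pq.empty()) {
    WsNode nd = pq.top();
    pq.pop();
    if (lab[nd.idx] == 0) {
      lab[nd.idx] = nd.label;
      expand(nd.idx, nd.label);
    }
  }
  return lab;
}
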