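#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Index helpers for column-major 3D arrays of dim (ny, nx, nz).
static inline R_xlen_t vox(int y, int x, int z, int ny, int nx) {
  return (R_xlen_t)z * ny * nx + (R_xlen_t)x * ny + y;
}

// Connected-component labelling of a binary volume (2D images are passed
// with nz = 1). connectivity = 1 labels face neighbours (4/6-connectivity),
// connectivity = 2 includes diagonals (8/26-connectivity). Flood fill with
// an explicit stack; labels are assigned in raster-scan order, which makes
// the labelling deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label(LogicalVector img, IntegerVector dim, int connectivity) {
  int ny = dim[0], nx = dim[1], nz = dim.size() > 2 ? dim[2] : 1;
  IntegerVector lab(img.size(), 0);
  std::vector<std::array<int, 3> > offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        if (dy == 0 && dx == 0 && dz == 0) continue;
        int manh = std::abs(dy) + std::abs(dx) + std::abs(dz);
        if (connectivity == 1 && manh > 1) continue;
        offs.push_back({dy, dx, dz});
      }
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        R_xlen_t i = vox(y, x, z, ny, nx);
        if (img[i] != TRUE || lab[i] != 0) continue;
        lab[i] = ++next;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          R_xlen_t c = stack.back();
          stack.pop_back();
          int cz = (int)(c / ((R_xlen_t)ny * nx));
          int rem = (int)(c % ((R_xlen_t)ny * nx));
          int cx = rem / ny, cy = rem % ny;
          for (size_t k = 0; k < offs.size(); ++k) {
            int yy = cy + offs[k][0], xx = cx + offs[k][1], zz = cz + offs[k][2];
            if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
              continue;
            R_xlen_t j = vox(yy, xx, zz, ny, nx);
            if (img[j] == TRUE && lab[j] == 0) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
        }
      }
  lab.attr("max_label") = next;
  return lab;
}

// Median filter with square window of half-width `radius`; NA pixels are
// excluded from each window, and a pixel that is itself NA stays NA (NA
// marks out-of-field regions after drift correction).
// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix img, int radius) {
  int ny = img.nrow(), nx = img.ncol();
  NumericMatrix out(ny, nx);
  std::vector<double> win;
  win.reserve((2 * radius + 1) * (2 * radius + 1));
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      if (NumericVector::is_na(img(y, x))) {
        out(y, x) = NA_REAL;
        continue;
      }
      win.clear();
      for (int dx = -radius; dx <= radius; ++dx)
        for (int dy = -radius; dy <= radius; ++dy) {
          int yy = y + dy, xx = x + dx;
          if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
          double v = img(yy, xx);
          if (!NumericVector::is_na(v)) win.push_back(v);
        }
      size_t n = win.size();
      std::nth_element(win.begin(), win.begin() + n / 2, win.end());
      double hi = win[n / 2];
      if (n % 2 == 1) {
        out(y, x) = hi;
      } else {
        double lo = *std::max_element(win.begin(), win.begin() + n / 2);
        out(y, x) = (lo + hi) / 2.0;
      }
    }
  return out;
}

// Greyscale dilation (box maximum) over a cube window; 2D with nz = 1.
// Separable: one sliding-window pass per axis. NA voxels are ignored.
// Erosion is obtained in R as -cpp_max_filter(-x, ...).
// [[Rcpp::export]]
NumericVector cpp_max_filter(NumericVector img, IntegerVector dim, int radius) {
  int ny = dim[0], nx = dim[1], nz = dim.size() > 2 ? dim[2] : 1;
  const double NEG = -std::numeric_limits<double>::infinity();
  std::vector<double> cur(img.size());
  for (R_xlen_t i = 0; i < img.size(); ++i)
    cur[i] = NumericVector::is_na(img[i]) ? NEG : img[i];
  std::vector<double> nxt(img.size());
  // y axis
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        double m = NEG;
        int lo = std::max(0, y - radius), hi = std::min(ny - 1, y + radius);
        for (int p = lo; p <= hi; ++p)
          m = std::max(m, cur[vox(p, x, z, ny, nx)]);
        nxt[vox(y, x, z, ny, nx)] = m;
      }
  cur.swap(nxt);
  // x axis
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      int lo = std::max(0, x - radius), hi = std::min(nx - 1, x + radius);
      for (int y = 0; y < ny; ++y) {
        double m = NEG;
        for (int p = lo; p <= hi; ++p)
          m = std::max(m, cur[vox(y, p, z, ny, nx)]);
        nxt[vox(y, x, z, ny, nx)] = m;
      }
    }
  cur.swap(nxt);
  // z axis
  if (nz > 1) {
    for (int z = 0; z < nz; ++z) {
      int lo = std::max(0, z - radius), hi = std::min(nz - 1, z + radius);
      for (int x = 0; x < nx; ++x)
        for (int y = 0; y < ny; ++y) {
          double m = NEG;
          for (int p = lo; p <= hi; ++p)
            m = std::max(m, cur[vox(y, x, p, ny, nx)]);
          nxt[vox(y, x, z, ny, nx)] = m;
        }
    }
    cur.swap(nxt);
  }
  NumericVector out(img.size());
  for (R_xlen_t i = 0; i < img.size(); ++i) out[i] = cur[i];
  return out;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher lower
// envelope of parabolas), used as a separable pass per axis.
static void dt1d(std::vector<double> &f, std::vector<double> &d, double step) {
  int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  int k = 0;
  v[0] = 0;
  zb[0] = -std::numeric_limits<double>::infinity();
  zb[1] = std::numeric_limits<double>::infinity();
  double s2 = step * step;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) / (2.0 * s2 * (q - p));
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = (double)(q - v[k]) * step;
    d[q] = dq * dq + f[v[k]];
  }
}

// Euclidean distance transform of a binary volume: distance from each
// foreground voxel to the nearest background (FALSE) voxel inside the
// volume, in physical units given per-axis spacings (sy, sx, sz). The
// volume edge itself is not treated as background.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector fg, IntegerVector dim, NumericVector spacing) {
  int ny = dim[0], nx = dim[1], nz = dim.size() > 2 ? dim[2] : 1;
  // large finite sentinel instead of infinity: keeps the parabola
  // envelope free of inf - inf = NaN while still dominating any real
  // squared distance
  const double BIG = 1e30;
  std::vector<double> g(fg.size());
  for (R_xlen_t i = 0; i < fg.size(); ++i) g[i] = fg[i] == TRUE ? BIG : 0.0;
  {
    std::vector<double> f(ny), d(ny);
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x) {
        for (int y = 0; y < ny; ++y) f[y] = g[vox(y, x, z, ny, nx)];
        dt1d(f, d, spacing[0]);
        for (int y = 0; y < ny; ++y) g[vox(y, x, z, ny, nx)] = d[y];
      }
  }
  {
    std::vector<double> f(nx), d(nx);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        for (int x = 0; x < nx; ++x) f[x] = g[vox(y, x, z, ny, nx)];
        dt1d(f, d, spacing[1]);
        for (int x = 0; x < nx; ++x) g[vox(y, x, z, ny, nx)] = d[x];
      }
  }
  if (nz > 1) {
    std::vector<double> f(nz), d(nz);
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        for (int z = 0; z < nz; ++z) f[z] = g[vox(y, x, z, ny, nx)];
        dt1d(f, d, spacing[2]);
        for (int z = 0; z < nz; ++z) g[vox(y, x, z, ny, nx)] = d[z];
      }
  }
  NumericVector out(fg.size());
  for (R_xlen_t i = 0; i < fg.size(); ++i)
    out[i] = g[i] >= BIG ? R_PosInf : std::sqrt(g[i]);
  return out;
}

struct WsNode {
  double prio;
  unsigned long order;
  R_xlen_t idx;
  int label;
};
struct WsCmp {
  bool operator()(const WsNode &a, const WsNode &b) const {
    if (a.prio != b.prio) return a.prio > b.prio; // min-heap on priority
    return a.order > b.order;                     // FIFO tie-break
  }
};

// Seeded watershed by priority flooding: voxels inside `mask` are flooded
// from the seed labels in increasing order of `prio` (pass -distance to
// grow basins from distance-transform maxima). Deterministic via FIFO
// tie-breaking on equal priority.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector prio, LogicalVector mask,
                            IntegerVector seeds, IntegerVector dim) {
  int ny = dim[0], nx = dim[1], nz = dim.size() > 2 ? dim[2] : 1;
  IntegerVector lab(clone(seeds));
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  unsigned long counter = 0;
  const int d6[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        R_xlen_t i = vox(y, x, z, ny, nx);
        if (lab[i] > 0) pq.push({prio[i], counter++, i, lab[i]});
      }
  while (!pq.empty()) {
    WsNode nd = pq.top();
    pq.pop();
    int cz = (int)(nd.idx / ((R_xlen_t)ny * nx));
    int rem = (int)(nd.idx % ((R_xlen_t)ny * nx));
    int cx = rem / ny, cy = rem % ny;
    for (int k = 0; k < 6; ++k) {
      int yy = cy + d6[k][0], xx = cx + d6[k][1], zz = cz + d6[k][2];
      if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
        continue;
      R_xlen_t j = vox(yy, xx, zz, ny, nx);
      if (mask[j] == TRUE && lab[j] == 0) {
        lab[j] = nd.label;
        pq.push({prio[j], counter++, j, nd.label});
      }
    }
  }
  return lab;
}

// Hungarian algorithm (Kuhn-Munkres with potentials, O(n^2 m)) for a
// square cost matrix. Returns, for each row, the 1-based assigned column.
// Costs must be finite; use a large sentinel for forbidden pairs and
// post-filter in R. Deterministic for a given matrix.
// [[Rcpp::export]]
IntegerVector cpp_hungarian(NumericMatrix cost) {
  int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = 0;
      double delta = INF;
      for (int j = 1; j <= n; ++j)
        if (!used[j]) {
          double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
          if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
          if (minv[j] < delta) { delta = minv[j]; j1 = j; }
        }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do {
      int j1 = way[j0];
      p[j0] = p[j1];
      j0 = j1;
    } while (j0);
  }
  IntegerVector ans(n, 0);
  for (int j = 1; j <= n; ++j)
    if (p[j] > 0) ans[p[j] - 1] = j;
  return ans;
}
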