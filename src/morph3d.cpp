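// Voxel geometry kernels: connected-component labeling (26-connectivity),
// exact anisotropic Euclidean distance transform (Felzenszwalb & Huttenlocher
// lower-envelope method per axis), separable Gaussian smoothing, and a
// marching-tetrahedra isosurfacer on the voxel-center lattice.
//
// Array convention matches the R side: dims = (nx, ny, nz), column-major,
// linear index i + nx*(j + ny*k); voxel (i,j,k) has its center at
// ((i+0.5)*dx, (j+0.5)*dy, (k+0.5)*dz) in physical units (nm).

#include <Rcpp.h>
#include <queue>
#include <unordered_map>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline R_xlen_t lin(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector labels(mask.size(), 0);
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < mask.size(); ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++next;
    labels[s] = next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      int k = (int)(v / ((R_xlen_t)nx * ny));
      int rem = (int)(v - (R_xlen_t)k * nx * ny);
      int j = rem / nx, i = rem % nx;
      for (int dk = -1; dk <= 1; ++dk) {
        int kk = k + dk; if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = j + dj; if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di; if (ii < 0 || ii >= nx) continue;
            R_xlen_t w = lin(ii, jj, kk, nx, ny);
            if (mask[w] && labels[w] == 0) { labels[w] = next; q.push(w); }
          }
        }
      }
    }
  }
  return labels;
}

// 1D squared-distance transform with sample spacing h (lower envelope of
// parabolas rooted at f[i] over positions x_i = i*h).
static void dt1d(const double* f, double* d, int n, double h,
                 int* v, double* z) {
  const double INF = std::numeric_limits<double>::infinity();
  // parabolas rooted at +inf never contribute; skip them so the
  // envelope arithmetic stays NaN-free (a whole line may be +inf)
  int first = 0;
  while (first < n && f[first] == INF) ++first;
  if (first == n) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int k = 0;
  v[0] = first;
  z[0] = -INF;
  z[1] = INF;
  for (int q = first + 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double s;
    for (;;) {
      double xq = q * h, xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * xq - 2.0 * xv);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * h;
    d[q] = dx * dx + f[v[k]];
  }
}

// Distance (physical units) from each foreground voxel center to the nearest
// background voxel center; 0 on background. Voxels outside the grid are
// treated as foreground (no implicit background border), so callers pad if
// they want the boundary to count.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dims,
                      NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector d2(mask.size());
  for (R_xlen_t s = 0; s < mask.size(); ++s) d2[s] = mask[s] ? INF : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i] = d2[lin(i, j, k, nx, ny)];
      dt1d(f.data(), d.data(), nx, spacing[0], v.data(), z.data());
      for (int i = 0; i < nx; ++i) d2[lin(i, j, k, nx, ny)] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = d2[lin(i, j, k, nx, ny)];
      dt1d(f.data(), d.data(), ny, spacing[1], v.data(), z.data());
      for (int j = 0; j < ny; ++j) d2[lin(i, j, k, nx, ny)] = d[j];
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = d2[lin(i, j, k, nx, ny)];
      dt1d(f.data(), d.data(), nz, spacing[2], v.data(), z.data());
      for (int k = 0; k < nz; ++k) d2[lin(i, j, k, nx, ny)] = d[k];
    }

  for (R_xlen_t s = 0; s < d2.size(); ++s) d2[s] = std::sqrt(d2[s]);
  return d2;
}

// Separable truncated Gaussian (3 sigma, zero padding beyond the grid).
// sigma given per axis in voxel units; sigma <= 0 skips that axis.
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector field, IntegerVector dims,
                               NumericVector sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector cur = clone(field);
  const int n_ax[3] = {nx, ny, nz};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> w(2 * r + 1);
    double tot = 0;
    for (int t = -r; t <= r; ++t) {
      w[t + r] = std::exp(-0.5 * t * t / (s * s));
      tot += w[t + r];
    }
    for (double& x : w) x /= tot;
    NumericVector out(cur.size(), 0.0);
    int n = n_ax[ax];
    R_xlen_t stride = (ax == 0) ? 1 : (ax == 1) ? nx : (R_xlen_t)nx * ny;
    // iterate all lines along axis ax
    int nA = (ax == 0) ? ny : nx;
    int nB = (ax == 2) ? ny : nz;
    for (int b = 0; b < nB; ++b)
      for (int a = 0; a < nA; ++a) {
        R_xlen_t base;
        if (ax == 0)      base = lin(0, a, b, nx, ny);
        else if (ax == 1) base = lin(a, 0, b, nx, ny);
        else              base = lin(a, b, 0, nx, ny);
        for (int p = 0; p < n; ++p) {
          double acc = 0;
          int lo = std::max(0, p - r), hi = std::min(n - 1, p + r);
          for (int t = lo; t <= hi; ++t)
            acc += w[t - p + r] * cur[base + stride * t];
          out[base + stride * p] = acc;
        }
      }
    cur = out;
  }
  return cur;
}

// --- marching tetrahedra -----------------------------------------------

// Six tetrahedra per cell sharing the main diagonal c0-c6; face diagonals
// agree between neighboring cells, so the output is watertight.
static const int TETS[6][4] = {
  {0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
  {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}
};
// corner c -> (dx, dy, dz) offsets within the cell
static const int COFF[8][3] = {
  {0,0,0}, {1,0,0}, {1,1,0}, {0,1,0},
  {0,0,1}, {1,0,1}, {1,1,1}, {0,1,1}
};

struct MTState {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> f1, f2, f3;
};

static int interp_vertex(MTState& st, R_xlen_t ga, R_xlen_t gb,
                         const double* pa, const double* pb,
                         double fa, double fb, double level) {
  uint64_t a = (uint64_t)ga, b = (uint64_t)gb;
  if (a > b) { std::swap(a, b); std::swap(pa, pb); std::swap(fa, fb); }
  uint64_t key = (a << 32) | b;
  auto it = st.edge_vertex.find(key);
  if (it != st.edge_vertex.end()) return it->second;
  double t = (level - fa) / (fb - fa);
  int id = (int)st.vx.size();
  st.vx.push_back(pa[0] + t * (pb[0] - pa[0]));
  st.vy.push_back(pa[1] + t * (pb[1] - pa[1]));
  st.vz.push_back(pa[2] + t * (pb[2] - pa[2]));
  st.edge_vertex.emplace(key, id);
  return id;
}

static void emit_tri(MTState& st, int a, int b, int c,
                     const double in_cent[3]) {
  // orient so the normal points away from the inside of the surface
  double ax = st.vx[a], ay = st.vy[a], az = st.vz[a];
  double ux = st.vx[b] - ax, uy = st.vy[b] - ay, uz = st.vz[b] - az;
  double wx = st.vx[c] - ax, wy = st.vy[c] - ay, wz = st.vz[c] - az;
  double nx_ = uy * wz - uz * wy;
  double ny_ = uz * wx - ux * wz;
  double nz_ = ux * wy - uy * wx;
  double cx = (ax + st.vx[b] + st.vx[c]) / 3.0 - in_cent[0];
  double cy = (ay + st.vy[b] + st.vy[c]) / 3.0 - in_cent[1];
  double cz = (az + st.vz[b] + st.vz[c]) / 3.0 - in_cent[2];
  if (nx_ * cx + ny_ * cy + nz_ * cz < 0) std::swap(b, c);
  st.f1.push_back(a + 1); st.f2.push_back(b + 1); st.f3.push_back(c + 1);
}

// [[Rcpp::export]]
List cpp_march_tets(NumericVector field, IntegerVector dims,
                    NumericVector spacing, double level) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double dx = spacing[0], dy = spacing[1], dz = spacing[2];
  MTState st;

  R_xlen_t gidx[8];
  double fval[8], pos[8][3];

  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + COFF[c][0], jj = j + COFF[c][1], kk = k + COFF[c][2];
          gidx[c] = lin(ii, jj, kk, nx, ny);
          fval[c] = field[gidx[c]];
          pos[c][0] = (ii + 0.5) * dx;
          pos[c][1] = (jj + 0.5) * dy;
          pos[c][2] = (kk + 0.5) * dz;
          (fval[c] > level ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          const int* T = TETS[t];
          int ins[4], outs[4], ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) {
            if (fval[T[c]] > level) ins[ni++] = T[c]; else outs[no++] = T[c];
          }
          if (ni == 0 || ni == 4) continue;
          double cen[3] = {0, 0, 0};
          for (int c = 0; c < ni; ++c)
            for (int d = 0; d < 3; ++d) cen[d] += pos[ins[c]][d] / ni;
          if (ni == 1) {
            int a = interp_vertex(st, gidx[ins[0]], gidx[outs[0]],
                                  pos[ins[0]], pos[outs[0]],
                                  fval[ins[0]], fval[outs[0]], level);
            int b = interp_vertex(st, gidx[ins[0]], gidx[outs[1]],
                                  pos[ins[0]], pos[outs[1]],
                                  fval[ins[0]], fval[outs[1]], level);
            int c = interp_vertex(st, gidx[ins[0]], gidx[outs[2]],
                                  pos[ins[0]], pos[outs[2]],
                                  fval[ins[0]], fval[outs[2]], level);
            emit_tri(st, a, b, c, cen);
          } else if (ni == 3) {
            int a = interp_vertex(st, gidx[ins[0]], gidx[outs[0]],
                                  pos[ins[0]], pos[outs[0]],
                                  fval[ins[0]], fval[outs[0]], level);
            int b = interp_vertex(st, gidx[ins[1]], gidx[outs[0]],
                                  pos[ins[1]], pos[outs[0]],
                                  fval[ins[1]], fval[outs[0]], level);
            int c = interp_vertex(st, gidx[ins[2]], gidx[outs[0]],
                                  pos[ins[2]], pos[outs[0]],
                                  fval[ins[2]], fval[outs[0]], level);
            emit_tri(st, a, b, c, cen);
          } else { // ni == 2
            int a = interp_vertex(st, gidx[ins[0]], gidx[outs[0]],
                                  pos[ins[0]], pos[outs[0]],
                                  fval[ins[0]], fval[outs[0]], level);
            int b = interp_vertex(st, gidx[ins[0]], gidx[outs[1]],
                                  pos[ins[0]], pos[outs[1]],
                                  fval[ins[0]], fval[outs[1]], level);
            int c = interp_vertex(st, gidx[ins[1]], gidx[outs[1]],
                                  pos[ins[1]], pos[outs[1]],
                                  fval[ins[1]], fval[outs[1]], level);
            int d = interp_vertex(st, gidx[ins[1]], gidx[outs[0]],
                                  pos[ins[1]], pos[outs[0]],
                                  fval[ins[1]], fval[outs[0]], level);
            emit_tri(st, a, b, c, cen);
            emit_tri(st, a, c, d, cen);
          }
        }
      }

  int nv = (int)st.vx.size(), nf = (int)st.f1.size();
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) {
    V(v, 0) = st.vx[v]; V(v, 1) = st.vy[v]; V(v, 2) = st.vz[v];
  }
  IntegerMatrix F(nf, 3);
  for (int f = 0; f < nf; ++f) {
    F(f, 0) = st.f1[f]; F(f, 1) = st.f2[f]; F(f, 2) = st.f3[f];
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
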