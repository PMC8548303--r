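// Geometry kernels: exact point-to-triangle-mesh queries (uniform-grid
// accelerated), parity ray-cast voxelization of closed meshes, 26-connected
// component labelling, and Taubin mesh smoothing.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <algorithm>
#include <limits>
using namespace Rcpp;

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void sub3(const double* a, const double* b, double* out) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}

// Closest point on triangle (a,b,c) to p; Ericson, Real-Time Collision
// Detection, 5.1.5.  Writes the closest point into out.
static void closest_pt_triangle(const double* p, const double* a,
                                const double* b, const double* c,
                                double* out) {
  double ab[3], ac[3], ap[3];
  sub3(b, a, ab); sub3(c, a, ac); sub3(p, a, ap);
  double d1 = dot3(ab, ap), d2 = dot3(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) { out[0]=a[0]; out[1]=a[1]; out[2]=a[2]; return; }

  double bp[3];
  sub3(p, b, bp);
  double d3 = dot3(ab, bp), d4 = dot3(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) { out[0]=b[0]; out[1]=b[1]; out[2]=b[2]; return; }

  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }

  double cp[3];
  sub3(p, c, cp);
  double d5 = dot3(ab, cp), d6 = dot3(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) { out[0]=c[0]; out[1]=c[1]; out[2]=c[2]; return; }

  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }

  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }

  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

// Uniform grid over triangle AABBs.
struct TriGrid {
  int nx, ny, nz;
  double h;            // cell edge
  double gmin[3];
  std::vector< std::vector<int> > cells;
  const double* V;     // 3 x nV column-major? stored as R matrix nV x 3
  int nV;
  const int* F;        // nF x 3 (0-based)
  int nF;

  inline int cidx(int i, int j, int k) const { return i + nx * (j + ny * k); }
  inline void cell_of(const double* p, int& i, int& j, int& k) const {
    i = (int)std::floor((p[0] - gmin[0]) / h);
    j = (int)std::floor((p[1] - gmin[1]) / h);
    k = (int)std::floor((p[2] - gmin[2]) / h);
    i = std::min(std::max(i, 0), nx - 1);
    j = std::min(std::max(j, 0), ny - 1);
    k = std::min(std::max(k, 0), nz - 1);
  }
  inline void vert(int vi, double* out) const {
    out[0] = V[vi]; out[1] = V[vi + nV]; out[2] = V[vi + 2 * nV];
  }
};

static void build_grid(TriGrid& g, const NumericMatrix& V,
                       const IntegerMatrix& F) {
  g.V = REAL(V); g.nV = V.nrow();
  g.F = INTEGER(F); g.nF = F.nrow();
  double lo[3] = { R_PosInf, R_PosInf, R_PosInf };
  double hi[3] = { R_NegInf, R_NegInf, R_NegInf };
  for (int d = 0; d < 3; ++d) {
    for (int i = 0; i < g.nV; ++i) {
      double x = g.V[i + d * g.nV];
      if (x < lo[d]) lo[d] = x;
      if (x > hi[d]) hi[d] = x;
    }
  }
  double ext = std::max(hi[0] - lo[0],
               std::max(hi[1] - lo[1], hi[2] - lo[2]));
  if (ext <= 0) ext = 1.0;
  // Aim for roughly nF occupied cells.
  int gdim = (int)std::ceil(std::cbrt((double)std::max(g.nF, 1)));
  gdim = std::min(std::max(gdim, 1), 128);
  g.h = ext / gdim;
  for (int d = 0; d < 3; ++d) g.gmin[d] = lo[d] - 1e-9;
  g.nx = std::max(1, (int)std::ceil((hi[0] - lo[0]) / g.h) + 1);
  g.ny = std::max(1, (int)std::ceil((hi[1] - lo[1]) / g.h) + 1);
  g.nz = std::max(1, (int)std::ceil((hi[2] - lo[2]) / g.h) + 1);
  g.cells.assign((size_t)g.nx * g.ny * g.nz, std::vector<int>());
  for (int f = 0; f < g.nF; ++f) {
    double tlo[3] = { R_PosInf, R_PosInf, R_PosInf };
    double thi[3] = { R_NegInf, R_NegInf, R_NegInf };
    for (int v = 0; v < 3; ++v) {
      int vi = g.F[f + v * g.nF];
      for (int d = 0; d < 3; ++d) {
        double x = g.V[vi + d * g.nV];
        if (x < tlo[d]) tlo[d] = x;
        if (x > thi[d]) thi[d] = x;
      }
    }
    int i0, j0, k0, i1, j1, k1;
    g.cell_of(tlo, i0, j0, k0);
    g.cell_of(thi, i1, j1, k1);
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i)
          g.cells[g.cidx(i, j, k)].push_back(f);
  }
}

static void query_point(const TriGrid& g, const double* p, double& best_d,
                        double* best_pt, int& best_f) {
  best_d = R_PosInf; best_f = -1;
  int ci, cj, ck;
  g.cell_of(p, ci, cj, ck);
  int rmax = std::max(g.nx, std::max(g.ny, g.nz));
  double a[3], b[3], c[3], q[3];
  for (int r = 0; r <= rmax; ++r) {
    // Cells farther than ring r are at least (r-1)*h away (p clamped into
    // its cell): once best_d <= (r-1)*h no farther ring can win.
    if (best_f >= 0 && best_d <= (double)(r - 1) * g.h) break;
    int i0 = std::max(ci - r, 0), i1 = std::min(ci + r, g.nx - 1);
    int j0 = std::max(cj - r, 0), j1 = std::min(cj + r, g.ny - 1);
    int k0 = std::max(ck - r, 0), k1 = std::min(ck + r, g.nz - 1);
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i) {
          int cheb = std::max(std::abs(i - ci),
                     std::max(std::abs(j - cj), std::abs(k - ck)));
          if (cheb != r) continue;  // only the shell
          const std::vector<int>& lst = g.cells[g.cidx(i, j, k)];
          for (size_t t = 0; t < lst.size(); ++t) {
            int f = lst[t];
            g.vert(g.F[f], a);
            g.vert(g.F[f + g.nF], b);
            g.vert(g.F[f + 2 * g.nF], c);
            closest_pt_triangle(p, a, b, c, q);
            double dx = q[0]-p[0], dy = q[1]-p[1], dz = q[2]-p[2];
            double d = std::sqrt(dx*dx + dy*dy + dz*dz);
            if (d < best_d) {
              best_d = d; best_f = f;
              best_pt[0]=q[0]; best_pt[1]=q[1]; best_pt[2]=q[2];
            }
          }
        }
  }
}

// [[Rcpp::export(name = ".cpp_closest_points")]]
List cpp_closest_points(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  TriGrid g;
  build_grid(g, V, F);
  int n = P.nrow();
  NumericVector dist(n);
  NumericMatrix closest(n, 3);
  IntegerVector face(n);
  double p[3], q[3];
  const double* Pp = REAL(P);
  for (int i = 0; i < n; ++i) {
    p[0] = Pp[i]; p[1] = Pp[i + n]; p[2] = Pp[i + 2 * n];
    double d; int f;
    query_point(g, p, d, q, f);
    dist[i] = d;
    face[i] = f + 1;  // 1-based for R
    closest(i, 0) = q[0]; closest(i, 1) = q[1]; closest(i, 2) = q[2];
  }
  return List::create(_["distance"] = dist, _["point"] = closest,
                      _["face"] = face);
}

// Parity ray-cast voxelization.  Voxel centre (i,j,k) (0-based) sits at
// origin + index * spacing.  Rays run along +x for every (j,k); a voxel is
// inside when its centre falls in an odd crossing interval.
// [[Rcpp::export(name = ".cpp_rasterize")]]
LogicalVector cpp_rasterize(NumericMatrix V, IntegerMatrix F,
                            int nx, int ny, int nz,
                            NumericVector origin, NumericVector spacing) {
  int nV = V.nrow(), nF = F.nrow();
  const double* Vp = REAL(V);
  const int* Fp = INTEGER(F);
  LogicalVector out((R_xlen_t)nx * ny * nz);
  std::fill(out.begin(), out.end(), FALSE);
  // Small irrational jitter keeps rays off vertices/edges.
  double jy = 0.5 * spacing[1] * 1.23456789e-4;
  double jz = 0.5 * spacing[2] * 0.98765433e-4;
  std::vector< std::vector<double> > cross((size_t)ny * nz);
  for (int f = 0; f < nF; ++f) {
    int ia = Fp[f], ib = Fp[f + nF], ic = Fp[f + 2 * nF];
    double ax = Vp[ia], ay = Vp[ia + nV], az = Vp[ia + 2 * nV];
    double bx = Vp[ib], by = Vp[ib + nV], bz = Vp[ib + 2 * nV];
    double cx = Vp[ic], cy = Vp[ic + nV], cz = Vp[ic + 2 * nV];
    double ylo = std::min(ay, std::min(by, cy));
    double yhi = std::max(ay, std::max(by, cy));
    double zlo = std::min(az, std::min(bz, cz));
    double zhi = std::max(az, std::max(bz, cz));
    int j0 = (int)std::ceil((ylo - origin[1] - jy) / spacing[1]);
    int j1 = (int)std::floor((yhi - origin[1] - jy) / spacing[1]);
    int k0 = (int)std::ceil((zlo - origin[2] - jz) / spacing[2]);
    int k1 = (int)std::floor((zhi - origin[2] - jz) / spacing[2]);
    j0 = std::max(j0, 0); j1 = std::min(j1, ny - 1);
    k0 = std::max(k0, 0); k1 = std::min(k1, nz - 1);
    double e1y = by - ay, e1z = bz - az;
    double e2y = cy - ay, e2z = cz - az;
    double det = e1y * e2z - e1z * e2y;   // projected (y,z) area * 2
    if (std::fabs(det) < 1e-300) continue; // ray-parallel triangle
    for (int k = k0; k <= k1; ++k) {
      double rz = origin[2] + k * spacing[2] + jz;
      for (int j = j0; j <= j1; ++j) {
        double ry = origin[1] + j * spacing[1] + jy;
        double py = ry - ay, pz = rz - az;
        double u = (py * e2z - pz * e2y) / det;
        double v = (e1y * pz - e1z * py) / det;
        if (u < 0.0 || v < 0.0 || u + v > 1.0) continue;
        double x = ax + u * (bx - ax) + v * (cx - ax);
        cross[(size_t)j + (size_t)ny * k].push_back(x);
      }
    }
  }
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      std::vector<double>& xs = cross[(size_t)j + (size_t)ny * k];
      if (xs.empty()) continue;
      std::sort(xs.begin(), xs.end());
      size_t m = xs.size() - (xs.size() % 2);  // drop unmatched crossing
      for (size_t t = 0; t + 1 < m; t += 2) {
        double x0 = xs[t], x1 = xs[t + 1];
        int i0 = (int)std::ceil((x0 - origin[0]) / spacing[0]);
        int i1 = (int)std::floor((x1 - origin[0]) / spacing[0]);
        i0 = std::max(i0, 0); i1 = std::min(i1, nx - 1);
        for (int i = i0; i <= i1; ++i)
          out[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = TRUE;
      }
    }
  return out;
}

// 26-connected component labelling of a logical 3D grid.
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(LogicalVector mask, int nx, int ny,
                                   int nz) {
  IntegerVector lab((R_xlen_t)nx * ny * nz);
  std::fill(lab.begin(), lab.end(), 0);
  int cur = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < mask.size(); ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    lab[s] = cur;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      int i = (int)(v % nx);
      int j = (int)((v / nx) % ny);
      int k = (int)(v / ((R_xlen_t)nx * ny));
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 ||
                ii >= nx || jj >= ny || kk >= nz) continue;
            R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            if (mask[w] && lab[w] == 0) { lab[w] = cur; q.push(w); }
          }
    }
  }
  return lab;
}

// Taubin lambda/mu smoothing with uniform weights (volume-preserving up to
// first order, unlike plain Laplacian shrinkage).
// [[Rcpp::export(name = ".cpp_taubin_smooth")]]
NumericMatrix cpp_taubin_smooth(NumericMatrix V, IntegerMatrix F, int iters,
                                double lambda, double mu) {
  int nV = V.nrow(), nF = F.nrow();
  std::vector< std::vector<int> > adj(nV);
  const int* Fp = INTEGER(F);
  for (int f = 0; f < nF; ++f) {
    int a = Fp[f], b = Fp[f + nF], c = Fp[f + 2 * nF];
    adj[a].push_back(b); adj[a].push_back(c);
    adj[b].push_back(a); adj[b].push_back(c);
    adj[c].push_back(a); adj[c].push_back(b);
  }
  for (int i = 0; i < nV; ++i) {
    std::sort(adj[i].begin(), adj[i].end());
    adj[i].erase(std::unique(adj[i].begin(), adj[i].end()), adj[i].end());
  }
  NumericMatrix X = clone(V);
  NumericMatrix Y(nV, 3);
  for (int it = 0; it < iters; ++it) {
    for (int pass = 0; pass < 2; ++pass) {
      double w = (pass == 0) ? lambda : mu;
      for (int i = 0; i < nV; ++i) {
        if (adj[i].empty()) {
          for (int d = 0; d < 3; ++d) Y(i, d) = X(i, d);
          continue;
        }
        for (int d = 0; d < 3; ++d) {
          double m = 0.0;
          for (size_t t = 0; t < adj[i].size(); ++t) m += X(adj[i][t], d);
          m /= (double)adj[i].size();
          Y(i, d) = X(i, d) + w * (m - X(i, d));
        }
      }
      std::copy(Y.begin(), Y.end(), X.begin());
    }
  }
  return X;
}
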