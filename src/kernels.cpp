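// Numerical kernels: separable stencil convolution (matrix-free Galerkin
// Poisson operator), tri-quadratic B-spline field evaluation, uniform-grid
// k-nearest-neighbour search, and exact point/segment/triangle distances.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Separable 3D convolution with centred odd-length 1D kernels, zero padding.
// out[i] = sum_m k[m] * x[i - m], m in [-h, h], applied axis by axis.
// ---------------------------------------------------------------------------

static void conv1d_axis(const std::vector<double>& in, std::vector<double>& out,
                        int nx, int ny, int nz, int axis, const NumericVector& k) {
  const int h = (k.size() - 1) / 2;
  const int n[3] = {nx, ny, nz};
  const long sx = 1, sy = nx, sz = (long)nx * ny;
  const long stride[3] = {sx, sy, sz};
  const long s = stride[axis];
  const int na = n[axis];
  std::fill(out.begin(), out.end(), 0.0);
  for (int iz = 0; iz < nz; ++iz) {
    for (int iy = 0; iy < ny; ++iy) {
      for (int ix = 0; ix < nx; ++ix) {
        const long idx = ix + (long)nx * iy + sz * iz;
        const int ia = (axis == 0) ? ix : (axis == 1 ? iy : iz);
        double acc = 0.0;
        const int mlo = std::max(-h, ia - (na - 1));
        const int mhi = std::min(h, ia);
        for (int m = mlo; m <= mhi; ++m)
          acc += k[m + h] * in[idx - m * s];
        out[idx] = acc;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3_sep(NumericVector x, IntegerVector dims,
                            NumericVector kx, NumericVector ky, NumericVector kz) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> a(x.begin(), x.end()), b(a.size());
  conv1d_axis(a, b, nx, ny, nz, 0, kx);
  conv1d_axis(b, a, nx, ny, nz, 1, ky);
  conv1d_axis(a, b, nx, ny, nz, 2, kz);
  NumericVector out(b.begin(), b.end());
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Quadratic B-spline (unit integral, support |t| < 1.5) and derivative.
// ---------------------------------------------------------------------------

static inline double bsp2(double t) {
  const double a = std::fabs(t);
  if (a >= 1.5) return 0.0;
  if (a <= 0.5) return 0.75 - t * t;
  const double u = 1.5 - a;
  return 0.5 * u * u;
}

static inline double bsp2d(double t) {
  const double a = std::fabs(t);
  if (a >= 1.5) return 0.0;
  if (a <= 0.5) return -2.0 * t;
  return (t > 0) ? -(1.5 - t) : (1.5 + t);
}

// Evaluate psi and grad psi at world points. coef is the depth-d node grid
// (node i centred at c0 + (i + 0.5) w per axis); psi = (1/w^3) sum c_i prod b.
// [[Rcpp::export]]
NumericMatrix cpp_field_eval(NumericVector coef, IntegerVector dims,
                             NumericVector c0, double w, NumericMatrix pts) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long sz = (long)nx * ny;
  const int np = pts.nrow();
  NumericMatrix out(np, 4);
  const double inv_w3 = 1.0 / (w * w * w);
  const double inv_w4 = inv_w3 / w;
  for (int p = 0; p < np; ++p) {
    const double t0 = (pts(p, 0) - c0[0]) / w - 0.5;
    const double t1 = (pts(p, 1) - c0[1]) / w - 0.5;
    const double t2 = (pts(p, 2) - c0[2]) / w - 0.5;
    const int x0 = std::max(0, (int)std::ceil(t0 - 1.5));
    const int x1 = std::min(nx - 1, (int)std::floor(t0 + 1.5));
    const int y0 = std::max(0, (int)std::ceil(t1 - 1.5));
    const int y1 = std::min(ny - 1, (int)std::floor(t1 + 1.5));
    const int z0 = std::max(0, (int)std::ceil(t2 - 1.5));
    const int z1 = std::min(nz - 1, (int)std::floor(t2 + 1.5));
    double psi = 0.0, gx = 0.0, gy = 0.0, gz = 0.0;
    for (int iz = z0; iz <= z1; ++iz) {
      const double bz = bsp2(t2 - iz), dz = bsp2d(t2 - iz);
      for (int iy = y0; iy <= y1; ++iy) {
        const double by = bsp2(t1 - iy), dy = bsp2d(t1 - iy);
        const double byz = by * bz;
        for (int ix = x0; ix <= x1; ++ix) {
          const double c = coef[ix + (long)nx * iy + sz * iz];
          if (c == 0.0) continue;
          const double bx = bsp2(t0 - ix), dx = bsp2d(t0 - ix);
          psi += c * bx * byz;
          gx += c * dx * byz;
          gy += c * bx * dy * bz;
          gz += c * bx * by * dz;
        }
      }
    }
    out(p, 0) = psi * inv_w3;
    out(p, 1) = gx * inv_w4;
    out(p, 2) = gy * inv_w4;
    out(p, 3) = gz * inv_w4;
  }
  return out;
}

// ---------------------------------------------------------------------------
// k-nearest neighbours via a uniform grid (Chebyshev ring expansion).
// Returns 1-based index matrix n x k; the query point itself is excluded
// (by index, so coincident duplicates remain eligible). Ties by index order.
// ---------------------------------------------------------------------------

static inline int64_t cell_key(int cx, int cy, int cz) {
  return ((int64_t)(cx + 1048576) << 42) | ((int64_t)(cy + 1048576) << 21) |
         (int64_t)(cz + 1048576);
}

// [[Rcpp::export]]
IntegerMatrix cpp_knn(NumericMatrix pts, int k) {
  const int n = pts.nrow();
  if (n <= k) stop("point cloud must contain more than k points");
  double lo[3], hi[3];
  for (int a = 0; a < 3; ++a) { lo[a] = R_PosInf; hi[a] = R_NegInf; }
  for (int i = 0; i < n; ++i)
    for (int a = 0; a < 3; ++a) {
      lo[a] = std::min(lo[a], pts(i, a));
      hi[a] = std::max(hi[a], pts(i, a));
    }
  double vol = 1.0, maxext = 1e-9;
  for (int a = 0; a < 3; ++a) {
    vol *= std::max(hi[a] - lo[a], 1e-9);
    maxext = std::max(maxext, hi[a] - lo[a]);
  }
  double h = std::cbrt(vol * 4.0 / n);
  if (!(h > 0) || !R_finite(h)) h = 1.0;
  // degenerate (collinear/coplanar) clouds collapse the volume estimate;
  // floor the cell size so the grid never exceeds 64 cells per axis
  h = std::max(h, maxext / 64.0);
  std::unordered_map<int64_t, std::vector<int>> grid;
  std::vector<int> ci(n), cj(n), ck(n);
  for (int i = 0; i < n; ++i) {
    ci[i] = (int)std::floor((pts(i, 0) - lo[0]) / h);
    cj[i] = (int)std::floor((pts(i, 1) - lo[1]) / h);
    ck[i] = (int)std::floor((pts(i, 2) - lo[2]) / h);
    grid[cell_key(ci[i], cj[i], ck[i])].push_back(i);
  }
  IntegerMatrix out(n, k);
  std::vector<std::pair<double, int>> cand;
  for (int q = 0; q < n; ++q) {
    cand.clear();
    const double qx = pts(q, 0), qy = pts(q, 1), qz = pts(q, 2);
    int r = 0;
    while (true) {
      // collect cells on Chebyshev shell of radius r around the query cell
      for (int dz = -r; dz <= r; ++dz)
        for (int dy = -r; dy <= r; ++dy)
          for (int dx = -r; dx <= r; ++dx) {
            if (std::max(std::abs(dx), std::max(std::abs(dy), std::abs(dz))) != r)
              continue;
            auto it = grid.find(cell_key(ci[q] + dx, cj[q] + dy, ck[q] + dz));
            if (it == grid.end()) continue;
            for (int j : it->second) {
              if (j == q) continue;
              const double ddx = pts(j, 0) - qx, ddy = pts(j, 1) - qy,
                           ddz = pts(j, 2) - qz;
              cand.push_back({ddx * ddx + ddy * ddy + ddz * ddz, j});
            }
          }
      if ((int)cand.size() >= k) {
        std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
        if (cand[k - 1].first <= (double)r * h * (double)r * h)
          break;
      }
      ++r;
      // once the rings cover the whole bounding box every point has been
      // visited; with n > k the candidate set is then complete
      if (r > (int)(maxext / h) + 2 && (int)cand.size() >= k) break;
      if (r > (int)(maxext / h) + 1000) stop("knn grid search failed");
    }
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    for (int j = 0; j < k; ++j) out(q, j) = cand[j].second + 1;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Exact closest-point distances: point-triangle, segment-segment,
// triangle-triangle, and point-to-mesh with a uniform acceleration grid.
// ---------------------------------------------------------------------------

static double pt_tri_dist2(const double* p, const double* a, const double* b,
                           const double* c) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i]; ac[i] = c[i] - a[i]; ap[i] = p[i] - a[i];
  }
  const double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  const double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  double q[3];
  if (d1 <= 0 && d2 <= 0) { for (int i = 0; i < 3; ++i) q[i] = a[i]; }
  else {
    double bp[3], cp[3];
    for (int i = 0; i < 3; ++i) { bp[i] = p[i] - b[i]; cp[i] = p[i] - c[i]; }
    const double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
    const double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
    const double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
    const double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
    if (d3 >= 0 && d4 <= d3) { for (int i = 0; i < 3; ++i) q[i] = b[i]; }
    else if (d6 >= 0 && d5 <= d6) { for (int i = 0; i < 3; ++i) q[i] = c[i]; }
    else {
      const double vc = d1 * d4 - d3 * d2;
      const double vb = d5 * d2 - d1 * d6;
      const double va = d3 * d6 - d5 * d4;
      if (vc <= 0 && d1 >= 0 && d3 <= 0) {
        const double v = d1 / (d1 - d3);
        for (int i = 0; i < 3; ++i) q[i] = a[i] + v * ab[i];
      } else if (vb <= 0 && d2 >= 0 && d6 <= 0) {
        const double v = d2 / (d2 - d6);
        for (int i = 0; i < 3; ++i) q[i] = a[i] + v * ac[i];
      } else if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
        const double v = (d4 - d3) / ((d4 - d3) + (d5 - d6));
        for (int i = 0; i < 3; ++i) q[i] = b[i] + v * (c[i] - b[i]);
      } else {
        const double denom = 1.0 / (va + vb + vc);
        const double v = vb * denom, w = vc * denom;
        for (int i = 0; i < 3; ++i) q[i] = a[i] + v * ab[i] + w * ac[i];
      }
    }
  }
  double d = 0;
  for (int i = 0; i < 3; ++i) { const double t = p[i] - q[i]; d += t * t; }
  return d;
}

static double seg_seg_dist2(const double* p1, const double* q1,
                            const double* p2, const double* q2) {
  double d1[3], d2[3], r[3];
  for (int i = 0; i < 3; ++i) {
    d1[i] = q1[i] - p1[i]; d2[i] = q2[i] - p2[i]; r[i] = p1[i] - p2[i];
  }
  const double a = d1[0]*d1[0] + d1[1]*d1[1] + d1[2]*d1[2];
  const double e = d2[0]*d2[0] + d2[1]*d2[1] + d2[2]*d2[2];
  const double f = d2[0]*r[0] + d2[1]*r[1] + d2[2]*r[2];
  double s, t;
  const double EPS = 1e-14;
  if (a <= EPS && e <= EPS) { s = t = 0.0; }
  else if (a <= EPS) { s = 0.0; t = std::min(1.0, std::max(0.0, f / e)); }
  else {
    const double c = d1[0]*r[0] + d1[1]*r[1] + d1[2]*r[2];
    if (e <= EPS) { t = 0.0; s = std::min(1.0, std::max(0.0, -c / a)); }
    else {
      const double b = d1[0]*d2[0] + d1[1]*d2[1] + d1[2]*d2[2];
      const double denom = a * e - b * b;
      s = (denom > EPS) ? std::min(1.0, std::max(0.0, (b * f - c * e) / denom)) : 0.0;
      t = (b * s + f) / e;
      if (t < 0) { t = 0; s = std::min(1.0, std::max(0.0, -c / a)); }
      else if (t > 1) { t = 1; s = std::min(1.0, std::max(0.0, (b - c) / a)); }
    }
  }
  double d = 0;
  for (int i = 0; i < 3; ++i) {
    const double u = (p1[i] + s * d1[i]) - (p2[i] + t * d2[i]);
    d += u * u;
  }
  return d;
}

// [[Rcpp::export]]
double cpp_tri_tri_dist(NumericVector t1, NumericVector t2) {
  const double* a[3] = {&t1[0], &t1[3], &t1[6]};
  const double* b[3] = {&t2[0], &t2[3], &t2[6]};
  double best = R_PosInf;
  for (int i = 0; i < 3; ++i) {
    best = std::min(best, pt_tri_dist2(a[i], b[0], b[1], b[2]));
    best = std::min(best, pt_tri_dist2(b[i], a[0], a[1], a[2]));
  }
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      best = std::min(best, seg_seg_dist2(a[i], a[(i + 1) % 3],
                                          b[j], b[(j + 1) % 3]));
  return std::sqrt(best);
}

// Minimum distance from each point to a triangle mesh (0-based faces are
// passed 1-based from R). Uniform grid over triangle bounding boxes.
// [[Rcpp::export]]
NumericVector cpp_point_mesh_dist(NumericMatrix pts, NumericMatrix V,
                                  IntegerMatrix F) {
  const int np = pts.nrow(), nf = F.nrow();
  if (nf == 0) stop("empty mesh");
  std::vector<double> tv(9 * (size_t)nf);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  double mean_edge = 0.0;
  for (int f = 0; f < nf; ++f) {
    for (int v = 0; v < 3; ++v) {
      const int vi = F(f, v) - 1;
      for (int a = 0; a < 3; ++a) {
        const double x = V(vi, a);
        tv[9 * (size_t)f + 3 * v + a] = x;
        lo[a] = std::min(lo[a], x); hi[a] = std::max(hi[a], x);
      }
    }
    double e = 0;
    for (int a = 0; a < 3; ++a) {
      const double d = tv[9 * (size_t)f + a] - tv[9 * (size_t)f + 3 + a];
      e += d * d;
    }
    mean_edge += std::sqrt(e);
  }
  mean_edge /= nf;
  double h = std::max(mean_edge * 2.0, 1e-9);
  std::unordered_map<int64_t, std::vector<int>> grid;
  for (int f = 0; f < nf; ++f) {
    double blo[3] = {R_PosInf, R_PosInf, R_PosInf};
    double bhi[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int v = 0; v < 3; ++v)
      for (int a = 0; a < 3; ++a) {
        blo[a] = std::min(blo[a], tv[9 * (size_t)f + 3 * v + a]);
        bhi[a] = std::max(bhi[a], tv[9 * (size_t)f + 3 * v + a]);
      }
    int c0[3], c1[3];
    for (int a = 0; a < 3; ++a) {
      c0[a] = (int)std::floor((blo[a] - lo[a]) / h);
      c1[a] = (int)std::floor((bhi[a] - lo[a]) / h);
    }
    for (int cz = c0[2]; cz <= c1[2]; ++cz)
      for (int cy = c0[1]; cy <= c1[1]; ++cy)
        for (int cx = c0[0]; cx <= c1[0]; ++cx)
          grid[cell_key(cx, cy, cz)].push_back(f);
  }
  std::vector<int> stamp(nf, -1);
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    const double q[3] = {pts(p, 0), pts(p, 1), pts(p, 2)};
    int cc[3];
    for (int a = 0; a < 3; ++a)
      cc[a] = (int)std::floor((q[a] - lo[a]) / h);
    double best2 = R_PosInf;
    int r = 0;
    const int rcap = 4 + (int)std::ceil(
        std::max(hi[0] - lo[0], std::max(hi[1] - lo[1], hi[2] - lo[2])) / h);
    while (true) {
      for (int dz = -r; dz <= r; ++dz)
        for (int dy = -r; dy <= r; ++dy)
          for (int dx = -r; dx <= r; ++dx) {
            if (std::max(std::abs(dx), std::max(std::abs(dy), std::abs(dz))) != r)
              continue;
            auto it = grid.find(cell_key(cc[0] + dx, cc[1] + dy, cc[2] + dz));
            if (it == grid.end()) continue;
            for (int f : it->second) {
              if (stamp[f] == p) continue;
              stamp[f] = p;
              best2 = std::min(best2, pt_tri_dist2(q, &tv[9 * (size_t)f],
                                                   &tv[9 * (size_t)f + 3],
                                                   &tv[9 * (size_t)f + 6]));
            }
          }
      const double safe = (double)r * h;
      if ((R_finite(best2) && best2 <= safe * safe) || r > rcap) break;
      ++r;
    }
    out[p] = std::sqrt(best2);
  }
  return out;
}
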