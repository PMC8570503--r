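// Low-level image primitives: connected-component labeling, separable
// Gaussian smoothing, marching-tetrahedra isosurface extraction, and rigid
// resampling. All arrays are column-major (R order), dims = (nx, ny, nz).
#include <Rcpp.h>
#include <queue>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline R_xlen_t idx3(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
}

// 3D connected components. connectivity: 6 or 26. Labels 1..K, 0 background.
// [[Rcpp::export(name = ".cpp_label3d")]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims,
                          int connectivity = 26) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector lab(mask.size(), 0);
  std::vector<std::array<int, 3>> nbr;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        int ad = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (connectivity == 6 && ad != 1) continue;
        nbr.push_back({di, dj, dk});
      }
  int current = 0;
  std::queue<std::array<int, 3>> q;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t p = idx3(i, j, k, nx, ny);
        if (!mask[p] || lab[p]) continue;
        lab[p] = ++current;
        q.push({i, j, k});
        while (!q.empty()) {
          auto v = q.front(); q.pop();
          for (const auto &d : nbr) {
            int ii = v[0] + d[0], jj = v[1] + d[1], kk = v[2] + d[2];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            R_xlen_t pp = idx3(ii, jj, kk, nx, ny);
            if (mask[pp] && !lab[pp]) { lab[pp] = current; q.push({ii, jj, kk}); }
          }
        }
      }
  lab.attr("n_components") = current;
  return lab;
}

// 2D connected components on a logical matrix, 8- or 4-connectivity.
// [[Rcpp::export(name = ".cpp_label2d")]]
IntegerMatrix cpp_label2d(LogicalMatrix mask, int connectivity = 8) {
  const int nx = mask.nrow(), ny = mask.ncol();
  IntegerMatrix lab(nx, ny);
  int current = 0;
  std::queue<std::pair<int, int>> q;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      lab(i, j) = ++current;
      q.push({i, j});
      while (!q.empty()) {
        auto v = q.front(); q.pop();
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            if (connectivity == 4 && std::abs(di) + std::abs(dj) != 1) continue;
            int ii = v.first + di, jj = v.second + dj;
            if (ii < 0 || jj < 0 || ii >= nx || jj >= ny) continue;
            if (mask(ii, jj) && !lab(ii, jj)) { lab(ii, jj) = current; q.push({ii, jj}); }
          }
      }
    }
  lab.attr("n_components") = current;
  return lab;
}

// Separable Gaussian smoothing, sigma in voxel units, zero (background)
// boundary condition; caller is expected to pad the array beforehand.
// [[Rcpp::export(name = ".cpp_smooth3d")]]
NumericVector cpp_smooth3d(NumericVector arr, IntegerVector dims, double sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> a(arr.begin(), arr.end());
  if (sigma > 0) {
    int r = (int)std::ceil(4.0 * sigma);
    std::vector<double> kern(2 * r + 1);
    double s = 0;
    for (int u = -r; u <= r; ++u) {
      kern[u + r] = std::exp(-0.5 * (u / sigma) * (u / sigma));
      s += kern[u + r];
    }
    for (auto &k : kern) k /= s;
    // axis 0 (x): lines vary i, fixed (j,k)
    {
      std::vector<double> line(nx);
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j) {
          for (int i = 0; i < nx; ++i) line[i] = a[idx3(i, j, k, nx, ny)];
          for (int i = 0; i < nx; ++i) {
            double acc = 0;
            for (int u = -r; u <= r; ++u) {
              int t = i + u;
              if (t >= 0 && t < nx) acc += kern[u + r] * line[t];
            }
            a[idx3(i, j, k, nx, ny)] = acc;
          }
        }
    }
    {
      std::vector<double> line(ny);
      for (int k = 0; k < nz; ++k)
        for (int i = 0; i < nx; ++i) {
          for (int j = 0; j < ny; ++j) line[j] = a[idx3(i, j, k, nx, ny)];
          for (int j = 0; j < ny; ++j) {
            double acc = 0;
            for (int u = -r; u <= r; ++u) {
              int t = j + u;
              if (t >= 0 && t < ny) acc += kern[u + r] * line[t];
            }
            a[idx3(i, j, k, nx, ny)] = acc;
          }
        }
    }
    {
      std::vector<double> line(nz);
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          for (int k = 0; k < nz; ++k) line[k] = a[idx3(i, j, k, nx, ny)];
          for (int k = 0; k < nz; ++k) {
            double acc = 0;
            for (int u = -r; u <= r; ++u) {
              int t = k + u;
              if (t >= 0 && t < nz) acc += kern[u + r] * line[t];
            }
            a[idx3(i, j, k, nx, ny)] = acc;
          }
        }
    }
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dims;
  return out;
}

// Marching tetrahedra. Each lattice cell is split into 6 tetrahedra around
// the main diagonal; the level surface of the per-tetrahedron linear
// interpolant is returned as a soup of triangles (one row per triangle,
// 9 columns: x1 y1 z1 x2 y2 z2 x3 y3 z3, in mm with voxel (0,0,0) center at
// the origin). "Inside" is field > level (strict).
// [[Rcpp::export(name = ".cpp_march_tets")]]
NumericMatrix cpp_march_tets(NumericVector field, IntegerVector dims,
                             double level, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double dx = spacing[0], dy = spacing[1], dz = spacing[2];
  // cube corner offsets, corner c = (i + bit0, j + bit1, k + bit2)
  static const int corner[8][3] = {
    {0,0,0},{1,0,0},{0,1,0},{1,1,0},{0,0,1},{1,0,1},{0,1,1},{1,1,1}};
  // 6-tet decomposition around diagonal corner0 - corner7
  static const int tets[6][4] = {
    {0,5,1,7},{0,1,3,7},{0,3,2,7},{0,2,6,7},{0,6,4,7},{0,4,5,7}};
  std::vector<double> tris;
  tris.reserve(1 << 16);
  double cx[8], cy[8], cz[8], cf[8];
  auto interp = [&](int a, int b, double *out) {
    double t = (level - cf[a]) / (cf[b] - cf[a]);
    out[0] = cx[a] + t * (cx[b] - cx[a]);
    out[1] = cy[a] + t * (cy[b] - cy[a]);
    out[2] = cz[a] + t * (cz[b] - cz[a]);
  };
  auto push_tri = [&](double *p, double *q, double *r) {
    tris.insert(tris.end(), {p[0], p[1], p[2], q[0], q[1], q[2], r[0], r[1], r[2]});
  };
  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + corner[c][0], jj = j + corner[c][1], kk = k + corner[c][2];
          cf[c] = field[idx3(ii, jj, kk, nx, ny)];
          cx[c] = ii * dx; cy[c] = jj * dy; cz[c] = kk * dz;
          (cf[c] > level ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          const int *v = tets[t];
          int in[4], nin = 0, out[4], nout = 0;
          for (int c = 0; c < 4; ++c)
            if (cf[v[c]] > level) in[nin++] = v[c]; else out[nout++] = v[c];
          if (nin == 0 || nin == 4) continue;
          double p1[3], p2[3], p3[3], p4[3];
          if (nin == 1) {
            interp(in[0], out[0], p1); interp(in[0], out[1], p2); interp(in[0], out[2], p3);
            push_tri(p1, p2, p3);
          } else if (nin == 3) {
            interp(in[0], out[0], p1); interp(in[1], out[0], p2); interp(in[2], out[0], p3);
            push_tri(p1, p2, p3);
          } else { // 2 in, 2 out -> quad
            interp(in[0], out[0], p1); interp(in[0], out[1], p2);
            interp(in[1], out[1], p3); interp(in[1], out[0], p4);
            push_tri(p1, p2, p3); push_tri(p1, p3, p4);
          }
        }
      }
  const R_xlen_t nT = (R_xlen_t)tris.size() / 9;
  NumericMatrix out((int)nT, 9);
  for (R_xlen_t r = 0; r < nT; ++r)
    for (int c = 0; c < 9; ++c) out(r, c) = tris[r * 9 + c];
  return out;
}

// Rigid resampling. M is a 3x4 matrix mapping OUTPUT world coordinates to
// INPUT world coordinates (row-major [R | t]). Output voxel centers are
// out_origin + index * out_spacing. method 0 = trilinear, 1 = nearest.
// [[Rcpp::export(name = ".cpp_resample_rigid")]]
NumericVector cpp_resample_rigid(NumericVector vol, IntegerVector dims,
                                 NumericVector spacing, NumericVector origin,
                                 NumericMatrix M, IntegerVector out_dims,
                                 NumericVector out_spacing, NumericVector out_origin,
                                 int method, double fill) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = out_dims[0], oy = out_dims[1], oz = out_dims[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i) {
        double wx = out_origin[0] + i * out_spacing[0];
        double wy = out_origin[1] + j * out_spacing[1];
        double wz = out_origin[2] + k * out_spacing[2];
        double sx = M(0,0)*wx + M(0,1)*wy + M(0,2)*wz + M(0,3);
        double sy = M(1,0)*wx + M(1,1)*wy + M(1,2)*wz + M(1,3);
        double sz = M(2,0)*wx + M(2,1)*wy + M(2,2)*wz + M(2,3);
        double fi = (sx - origin[0]) / spacing[0];
        double fj = (sy - origin[1]) / spacing[1];
        double fk = (sz - origin[2]) / spacing[2];
        double val = fill;
        if (method == 1) {
          int ii = (int)std::lround(fi), jj = (int)std::lround(fj), kk = (int)std::lround(fk);
          if (ii >= 0 && jj >= 0 && kk >= 0 && ii < nx && jj < ny && kk < nz)
            val = vol[idx3(ii, jj, kk, nx, ny)];
        } else {
          int i0 = (int)std::floor(fi), j0 = (int)std::floor(fj), k0 = (int)std::floor(fk);
          if (i0 >= 0 && j0 >= 0 && k0 >= 0 && i0 < nx - 1 && j0 < ny - 1 && k0 < nz - 1) {
            double tx = fi - i0, ty = fj - j0, tz = fk - k0;
            double acc = 0;
            for (int dk2 = 0; dk2 <= 1; ++dk2)
              for (int dj2 = 0; dj2 <= 1; ++dj2)
                for (int di2 = 0; di2 <= 1; ++di2) {
                  double w = (di2 ? tx : 1 - tx) * (dj2 ? ty : 1 - ty) * (dk2 ? tz : 1 - tz);
                  acc += w * vol[idx3(i0 + di2, j0 + dj2, k0 + dk2, nx, ny)];
                }
            acc += 0.0;
            val = acc;
          } else if (i0 >= -1 && j0 >= -1 && k0 >= -1 && i0 <= nx - 1 && j0 <= ny - 1 && k0 <= nz - 1) {
            // partially outside: clamp-sample with fill outside
            double tx = fi - i0, ty = fj - j0, tz = fk - k0;
            double acc = 0;
            for (int dk2 = 0; dk2 <= 1; ++dk2)
              for (int dj2 = 0; dj2 <= 1; ++dj2)
                for (int di2 = 0; di2 <= 1; ++di2) {
                  double w = (di2 ? tx : 1 - tx) * (dj2 ? ty : 1 - ty) * (dk2 ? tz : 1 - tz);
                  int ii = i0 + di2, jj = j0 + dj2, kk = k0 + dk2;
                  double v = (ii >= 0 && jj >= 0 && kk >= 0 && ii < nx && jj < ny && kk < nz)
                                 ? vol[idx3(ii, jj, kk, nx, ny)] : fill;
                  acc += w * v;
                }
            val = acc;
          }
        }
        out[idx3(i, j, k, ox, oy)] = val;
      }
  out.attr("dim") = out_dims;
  return out;
}
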