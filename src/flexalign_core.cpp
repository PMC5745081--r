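#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Conventions shared with the R layer:
//  * cubic volumes indexed [x, y, z], x fastest (MRC2014 section order);
//  * the coordinate origin sits at 0-based voxel N/2 (the FFT centre);
//  * orientations map reference-frame vectors v to projection-frame
//    vectors u = M v, and projections integrate along u_z.

static inline double trilinear(const double *v, int n, double x, double y,
                               double z) {
  // x,y,z are 0-based fractional voxel coordinates; outside -> 0
  if (x < 0 || y < 0 || z < 0 || x > n - 1 || y > n - 1 || z > n - 1)
    return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  int x1 = x0 + 1 < n ? x0 + 1 : x0;
  int y1 = y0 + 1 < n ? y0 + 1 : y0;
  int z1 = z0 + 1 < n ? z0 + 1 : z0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  const double *p00 = v + (size_t)z0 * n * n, *p01 = v + (size_t)z1 * n * n;
  double c000 = p00[y0 * n + x0], c100 = p00[y0 * n + x1];
  double c010 = p00[y1 * n + x0], c110 = p00[y1 * n + x1];
  double c001 = p01[y0 * n + x0], c101 = p01[y0 * n + x1];
  double c011 = p01[y1 * n + x0], c111 = p01[y1 * n + x1];
  double c00 = c000 + fx * (c100 - c000), c10 = c010 + fx * (c110 - c010);
  double c01 = c001 + fx * (c101 - c001), c11 = c011 + fx * (c111 - c011);
  double c0 = c00 + fy * (c10 - c00), c1 = c01 + fy * (c11 - c01);
  return c0 + fz * (c1 - c0);
}

static inline double bilinear(const double *img, int n, double x, double y) {
  if (x < 0 || y < 0 || x > n - 1 || y > n - 1) return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  int x1 = x0 + 1 < n ? x0 + 1 : x0;
  int y1 = y0 + 1 < n ? y0 + 1 : y0;
  double fx = x - x0, fy = y - y0;
  double c00 = img[y0 * n + x0], c10 = img[y0 * n + x1];
  double c01 = img[y1 * n + x0], c11 = img[y1 * n + x1];
  double c0 = c00 + fx * (c10 - c00), c1 = c01 + fx * (c11 - c01);
  return c0 + fy * (c1 - c0);
}

// Real-space line-integral projection of a cubic volume.
// R maps reference -> projection frame (u = R v); the image value at
// projection coordinate (ux,uy) is the integral over uz of
// vol(R^T (ux,uy,uz)), sampled at unit steps with trilinear
// interpolation. (dx,dy) shifts the projected content by +(dx,dy) px.
// rmax bounds the support radius of the volume (voxels from centre);
// rays outside it are exactly zero.
// [[Rcpp::export]]
NumericMatrix cpp_project(NumericVector vol, NumericMatrix R, double dx,
                          double dy, int out_n, double rmax) {
  IntegerVector d = vol.attr("dim");
  int n = d[0];
  const double *v = vol.begin();
  double c = n / 2, co = out_n / 2;
  double r11 = R(0, 0), r12 = R(0, 1), r13 = R(0, 2);
  double r21 = R(1, 0), r22 = R(1, 1), r23 = R(1, 2);
  double r31 = R(2, 0), r32 = R(2, 1), r33 = R(2, 2);
  NumericMatrix out(out_n, out_n);
  double r2max = rmax * rmax;
  for (int j = 0; j < out_n; ++j) {
    double uy = j - co - dy;
    for (int i = 0; i < out_n; ++i) {
      double ux = i - co - dx;
      double rr = ux * ux + uy * uy;
      if (rr > r2max) continue;
      double zext = std::sqrt(r2max - rr);
      int z0 = (int)std::ceil(-zext), z1 = (int)std::floor(zext);
      // v = R^T u (rows of R are the projection axes in the ref frame)
      double bx = r11 * ux + r21 * uy + c;
      double by = r12 * ux + r22 * uy + c;
      double bz = r13 * ux + r23 * uy + c;
      double s = 0.0;
      // fast path: whole ray strictly inside the grid -> no bounds
      // checks per sample
      double lox = bx + (r31 > 0 ? r31 * z0 : r31 * z1);
      double hix = bx + (r31 > 0 ? r31 * z1 : r31 * z0);
      double loy = by + (r32 > 0 ? r32 * z0 : r32 * z1);
      double hiy = by + (r32 > 0 ? r32 * z1 : r32 * z0);
      double loz = bz + (r33 > 0 ? r33 * z0 : r33 * z1);
      double hiz = bz + (r33 > 0 ? r33 * z1 : r33 * z0);
      if (lox >= 0 && loy >= 0 && loz >= 0 && hix < n - 1 &&
          hiy < n - 1 && hiz < n - 1) {
        double x = bx + r31 * z0, y = by + r32 * z0, z = bz + r33 * z0;
        for (int zz = z0; zz <= z1; ++zz) {
          int x0 = (int)x, y0 = (int)y, zi = (int)z;
          double fx = x - x0, fy = y - y0, fz = z - zi;
          const double *p00 = v + ((size_t)zi * n + y0) * n + x0;
          const double *p10 = p00 + n;
          const double *p01 = p00 + (size_t)n * n;
          const double *p11 = p01 + n;
          double c00 = p00[0] + fx * (p00[1] - p00[0]);
          double c10 = p10[0] + fx * (p10[1] - p10[0]);
          double c01 = p01[0] + fx * (p01[1] - p01[0]);
          double c11 = p11[0] + fx * (p11[1] - p11[0]);
          double a0 = c00 + fy * (c10 - c00);
          double a1 = c01 + fy * (c11 - c01);
          s += a0 + fz * (a1 - a0);
          x += r31; y += r32; z += r33;
        }
      } else {
        for (int z = z0; z <= z1; ++z)
          s += trilinear(v, n, bx + r31 * z, by + r32 * z,
                         bz + r33 * z);
      }
      out(i, j) = s;
    }
  }
  return out;
}

// out(v) = vol(R v + t), v in out-box centred coordinates, t in voxels.
// Serves volume rotation (R = M^T, t = 0) and module re-boxing
// (R = I, t = module centre).
// [[Rcpp::export]]
NumericVector cpp_resample_volume(NumericVector vol, NumericMatrix R,
                                  NumericVector t, int out_n) {
  IntegerVector d = vol.attr("dim");
  int n = d[0];
  const double *v = vol.begin();
  double c = n / 2, co = out_n / 2;
  NumericVector out((size_t)out_n * out_n * out_n);
  out.attr("dim") = IntegerVector::create(out_n, out_n, out_n);
  double *o = out.begin();
  for (int k = 0; k < out_n; ++k) {
    double z = k - co;
    for (int j = 0; j < out_n; ++j) {
      double y = j - co;
      for (int i = 0; i < out_n; ++i) {
        double x = i - co;
        double sx = R(0, 0) * x + R(0, 1) * y + R(0, 2) * z + t[0] + c;
        double sy = R(1, 0) * x + R(1, 1) * y + R(1, 2) * z + t[1] + c;
        double sz = R(2, 0) * x + R(2, 1) * y + R(2, 2) * z + t[2] + c;
        o[((size_t)k * out_n + j) * out_n + i] = trilinear(v, n, sx, sy, sz);
      }
    }
  }
  return out;
}

// Rotate image content counter-clockwise by angle_deg about the box
// centre (0-based pixel n/2), bilinear interpolation.
// [[Rcpp::export]]
NumericMatrix cpp_rotate_image(NumericMatrix img, double angle_deg) {
  int n = img.nrow();
  double a = angle_deg * M_PI / 180.0, ca = std::cos(a), sa = std::sin(a);
  double c = n / 2;
  NumericMatrix out(n, n);
  const double *p = img.begin();
  for (int j = 0; j < n; ++j) {
    double y = j - c;
    for (int i = 0; i < n; ++i) {
      double x = i - c;
      // content rotated by +a  <=>  sample source at R(-a) p
      double sx = ca * x + sa * y + c;
      double sy = -sa * x + ca * y + c;
      out(i, j) = bilinear(p, n, sx, sy);
    }
  }
  return out;
}

// Polar resampling about the box centre: rows = n_ang angles in
// [0, 2pi), cols = radii r0..r1 at unit steps.
// [[Rcpp::export]]
NumericMatrix cpp_polar_transform(NumericMatrix img, int n_ang, double r0,
                                  double r1) {
  int n = img.nrow();
  int n_rad = (int)std::floor(r1 - r0) + 1;
  double c = n / 2;
  NumericMatrix out(n_ang, n_rad);
  const double *p = img.begin();
  for (int a = 0; a < n_ang; ++a) {
    double th = 2.0 * M_PI * a / n_ang, ct = std::cos(th), st = std::sin(th);
    for (int r = 0; r < n_rad; ++r) {
      double rad = r0 + r;
      out(a, r) = bilinear(p, n, c + rad * ct, c + rad * st);
    }
  }
  return out;
}

// Per-voxel Pearson correlation of two volumes over a cubic window of
// odd side w. Voxels whose window has (near-)zero variance in either
// volume get cc 0 and flag 0.
// [[Rcpp::export]]
List cpp_local_cc(NumericVector a, NumericVector b, int w) {
  IntegerVector d = a.attr("dim");
  int n = d[0], h = w / 2;
  const double *pa = a.begin(), *pb = b.begin();
  size_t tot = (size_t)n * n * n;
  NumericVector cc(tot);
  IntegerVector flag(tot);
  cc.attr("dim") = d;
  flag.attr("dim") = d;
  // scale-aware variance floor: windows whose variance is at rounding
  // level relative to the map scale are treated as flat
  double msqa = 0, msqb = 0;
  for (size_t t = 0; t < tot; ++t) { msqa += pa[t] * pa[t]; msqb += pb[t] * pb[t]; }
  msqa /= tot; msqb /= tot;
  double floora = std::max(1e-30, 1e-9 * msqa * w * w * w);
  double floorb = std::max(1e-30, 1e-9 * msqb * w * w * w);
  for (int k = 0; k < n; ++k)
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i) {
        int i0 = std::max(0, i - h), i1 = std::min(n - 1, i + h);
        int j0 = std::max(0, j - h), j1 = std::min(n - 1, j + h);
        int k0 = std::max(0, k - h), k1 = std::min(n - 1, k + h);
        double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
        int m = 0;
        for (int kk = k0; kk <= k1; ++kk)
          for (int jj = j0; jj <= j1; ++jj) {
            size_t base = ((size_t)kk * n + jj) * n;
            for (int ii = i0; ii <= i1; ++ii) {
              double va = pa[base + ii], vb = pb[base + ii];
              sa += va; sb += vb;
              saa += va * va; sbb += vb * vb; sab += va * vb;
              ++m;
            }
          }
        double va = saa - sa * sa / m, vb = sbb - sb * sb / m;
        size_t idx = ((size_t)k * n + j) * n + i;
        if (va > floora && vb > floorb) {
          cc[idx] = (sab - sa * sb / m) / std::sqrt(va * vb);
          flag[idx] = 1;
        }
      }
  return List::create(_["cc"] = cc, _["flag"] = flag);
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher lower
// envelope), applied separably over the three axes.
static void edt_1d(std::vector<double> &f, std::vector<double> &d,
                   std::vector<int> &v, std::vector<double> &z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -1e20;
  z[1] = 1e20;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k] && k > 0) --k; else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = 1e20;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Squared Euclidean distance (in voxels) from every voxel to the
// nearest voxel where mask != 0.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(NumericVector mask) {
  IntegerVector d = mask.attr("dim");
  int n = d[0];
  size_t tot = (size_t)n * n * n;
  NumericVector out(tot);
  out.attr("dim") = d;
  double *o = out.begin();
  const double *m = mask.begin();
  for (size_t i = 0; i < tot; ++i) o[i] = m[i] != 0 ? 0.0 : 1e20;
  std::vector<double> f(n), dd(n), z(n + 1);
  std::vector<int> v(n);
  // pass along x
  for (int k = 0; k < n; ++k)
    for (int j = 0; j < n; ++j) {
      double *row = o + ((size_t)k * n + j) * n;
      for (int i = 0; i < n; ++i) f[i] = row[i];
      edt_1d(f, dd, v, z, n);
      for (int i = 0; i < n; ++i) row[i] = dd[i];
    }
  // pass along y
  for (int k = 0; k < n; ++k)
    for (int i = 0; i < n; ++i) {
      double *col = o + (size_t)k * n * n + i;
      for (int j = 0; j < n; ++j) f[j] = col[(size_t)j * n];
      edt_1d(f, dd, v, z, n);
      for (int j = 0; j < n; ++j) col[(size_t)j * n] = dd[j];
    }
  // pass along z
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i) {
      double *col = o + (size_t)j * n + i;
      for (int k = 0; k < n; ++k) f[k] = col[(size_t)k * n * n];
      edt_1d(f, dd, v, z, n);
      for (int k = 0; k < n; ++k) col[(size_t)k * n * n] = dd[k];
    }
  return out;
}

// Fourier-slice insertion for reconstruction. fre/fim hold centred 2D
// transforms of K images (n x n x K); Rarr is 9 x K (column-major 3x3
// per image, reference -> projection). Each slice sample at centred
// frequency (kx,ky) is spread trilinearly at g = R^T (kx,ky,0) into the
// centred 3D accumulator, together with its Hermitian mate at -g.
// [[Rcpp::export]]
List cpp_insert_slices(NumericVector fre, NumericVector fim,
                       NumericMatrix Rarr, double kmax) {
  IntegerVector d = fre.attr("dim");
  int n = d[0], K = d[2];
  double c = n / 2;
  NumericVector re((size_t)n * n * n), im((size_t)n * n * n),
      wt((size_t)n * n * n);
  re.attr("dim") = IntegerVector::create(n, n, n);
  im.attr("dim") = re.attr("dim");
  wt.attr("dim") = re.attr("dim");
  double *pr = re.begin(), *pi = im.begin(), *pw = wt.begin();
  const double *er = fre.begin(), *ei = fim.begin();
  double k2max = kmax * kmax;
  for (int s = 0; s < K; ++s) {
    const double *R = &Rarr(0, s);  // column-major 3x3
    for (int j = 0; j < n; ++j) {
      double ky = j - c;
      for (int i = 0; i < n; ++i) {
        double kx = i - c;
        if (kx * kx + ky * ky > k2max) continue;
        double gx = R[0] * kx + R[1] * ky;  // R^T (kx,ky,0)
        double gy = R[3] * kx + R[4] * ky;
        double gz = R[6] * kx + R[7] * ky;
        size_t sidx = ((size_t)s * n + j) * n + i;
        double vr = er[sidx], vi = ei[sidx];
        for (int herm = 0; herm < 2; ++herm) {
          double x = (herm ? -gx : gx) + c, y = (herm ? -gy : gy) + c,
                 z = (herm ? -gz : gz) + c;
          double vvi = herm ? -vi : vi;
          int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
              z0 = (int)std::floor(z);
          double fx = x - x0, fy = y - y0, fz = z - z0;
          for (int dz = 0; dz < 2; ++dz) {
            int zz = z0 + dz;
            if (zz < 0 || zz >= n) continue;
            double wz = dz ? fz : 1 - fz;
            for (int dyy = 0; dyy < 2; ++dyy) {
              int yy = y0 + dyy;
              if (yy < 0 || yy >= n) continue;
              double wy = dyy ? fy : 1 - fy;
              for (int dxx = 0; dxx < 2; ++dxx) {
                int xx = x0 + dxx;
                if (xx < 0 || xx >= n) continue;
                double wgt = wz * wy * (dxx ? fx : 1 - fx);
                size_t idx = ((size_t)zz * n + yy) * n + xx;
                pr[idx] += wgt * vr;
                pi[idx] += wgt * vvi;
                pw[idx] += wgt;
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["re"] = re, _["im"] = im, _["wt"] = wt);
}
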