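// Volume filtering and resampling primitives shared by the synthetic
// generator, the ventricle-mask features and the visualization module.
// All arrays are R 3D arrays with dim c(Z, Y, X); linear index z fastest.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

inline int reflect_idx(int i, int n) {
  // reflect-101 boundary (a b c | b a)
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

std::vector<double> gauss_kernel(double sigma) {
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (auto& v : k) v /= s;
  return k;
}

// convolve along one axis (0=z,1=y,2=x) with reflect boundary
void conv_axis(std::vector<double>& data, int Z, int Y, int X, int axis,
               const std::vector<double>& ker) {
  int n = axis == 0 ? Z : (axis == 1 ? Y : X);
  long stride = axis == 0 ? 1 : (axis == 1 ? (long)Z : (long)Z * Y);
  int r = ((int)ker.size() - 1) / 2;
  std::vector<double> line(n);
  long nlines = (long)Z * Y * X / n;
  // iterate all lines along the axis
  int d1 = axis == 0 ? Y : Z;
  long s1 = axis == 0 ? (long)Z : 1;
  int d2 = axis == 2 ? Y : X;
  long s2 = axis == 2 ? (long)Z : (long)Z * Y;
  (void)nlines;
  for (int b = 0; b < d2; ++b)
    for (int a = 0; a < d1; ++a) {
      long off = a * s1 + b * s2;
      for (int i = 0; i < n; ++i) line[i] = data[off + i * stride];
      for (int i = 0; i < n; ++i) {
        double acc = 0;
        for (int j = -r; j <= r; ++j)
          acc += ker[j + r] * line[reflect_idx(i + j, n)];
        data[off + i * stride] = acc;
      }
    }
}

}  // namespace

// Separable Gaussian smoothing; sigmas given per axis in voxels.
// [[Rcpp::export]]
NumericVector gauss3d_cpp(NumericVector arr, NumericVector sigma_vox) {
  IntegerVector dim = arr.attr("dim");
  int Z = dim[0], Y = dim[1], X = dim[2];
  std::vector<double> data(arr.begin(), arr.end());
  for (int a = 0; a < 3; ++a) {
    if (sigma_vox[a] > 1e-8) conv_axis(data, Z, Y, X, a, gauss_kernel(sigma_vox[a]));
  }
  NumericVector out(data.begin(), data.end());
  out.attr("dim") = dim;
  return out;
}

// Central-difference gradient magnitude with per-axis spacing.
// [[Rcpp::export]]
NumericVector gradmag3d_cpp(NumericVector arr, NumericVector spacing) {
  IntegerVector dim = arr.attr("dim");
  int Z = dim[0], Y = dim[1], X = dim[2];
  NumericVector out(arr.size());
  long ZY = (long)Z * Y;
  for (int x = 0; x < X; ++x)
    for (int y = 0; y < Y; ++y)
      for (int z = 0; z < Z; ++z) {
        long v = z + (long)Z * y + ZY * x;
        double gz = (arr[reflect_idx(z + 1, Z) + (long)Z * y + ZY * x] -
                     arr[reflect_idx(z - 1, Z) + (long)Z * y + ZY * x]) /
                    (2.0 * spacing[0]);
        double gy = (arr[z + (long)Z * reflect_idx(y + 1, Y) + ZY * x] -
                     arr[z + (long)Z * reflect_idx(y - 1, Y) + ZY * x]) /
                    (2.0 * spacing[1]);
        double gx = (arr[z + (long)Z * y + ZY * reflect_idx(x + 1, X)] -
                     arr[z + (long)Z * y + ZY * reflect_idx(x - 1, X)]) /
                    (2.0 * spacing[2]);
        out[v] = std::sqrt(gz * gz + gy * gy + gx * gx);
      }
  out.attr("dim") = dim;
  return out;
}

// 6-neighbour discrete Laplacian with per-axis spacing.
// [[Rcpp::export]]
NumericVector laplacian3d_cpp(NumericVector arr, NumericVector spacing) {
  IntegerVector dim = arr.attr("dim");
  int Z = dim[0], Y = dim[1], X = dim[2];
  NumericVector out(arr.size());
  long ZY = (long)Z * Y;
  for (int x = 0; x < X; ++x)
    for (int y = 0; y < Y; ++y)
      for (int z = 0; z < Z; ++z) {
        long v = z + (long)Z * y + ZY * x;
        double c = arr[v];
        double lz = (arr[reflect_idx(z + 1, Z) + (long)Z * y + ZY * x] +
                     arr[reflect_idx(z - 1, Z) + (long)Z * y + ZY * x] -
                     2 * c) / (spacing[0] * spacing[0]);
        double ly = (arr[z + (long)Z * reflect_idx(y + 1, Y) + ZY * x] +
                     arr[z + (long)Z * reflect_idx(y - 1, Y) + ZY * x] -
                     2 * c) / (spacing[1] * spacing[1]);
        double lx = (arr[z + (long)Z * y + ZY * reflect_idx(x + 1, X)] +
                     arr[z + (long)Z * y + ZY * reflect_idx(x - 1, X)] -
                     2 * c) / (spacing[2] * spacing[2]);
        out[v] = lz + ly + lx;
      }
  out.attr("dim") = dim;
  return out;
}

// Anti-aliased downsampling to an isotropic grid by averaging all input
// voxels whose centers fall inside each output voxel's physical box.
// [[Rcpp::export]]
List box_downsample_cpp(NumericVector arr, NumericVector spacing,
                        double target_um) {
  IntegerVector dim = arr.attr("dim");
  int Z = dim[0], Y = dim[1], X = dim[2];
  int Zo = (int)std::ceil(Z * spacing[0] / target_um);
  int Yo = (int)std::ceil(Y * spacing[1] / target_um);
  int Xo = (int)std::ceil(X * spacing[2] / target_um);
  long No = (long)Zo * Yo * Xo;
  std::vector<double> acc(No, 0.0);
  std::vector<double> cnt(No, 0.0);
  long ZY = (long)Z * Y;
  for (int x = 0; x < X; ++x) {
    int xo = std::min(Xo - 1, (int)(((x + 0.5) * spacing[2]) / target_um));
    for (int y = 0; y < Y; ++y) {
      int yo = std::min(Yo - 1, (int)(((y + 0.5) * spacing[1]) / target_um));
      for (int z = 0; z < Z; ++z) {
        int zo = std::min(Zo - 1, (int)(((z + 0.5) * spacing[0]) / target_um));
        long vo = zo + (long)Zo * yo + (long)Zo * Yo * xo;
        acc[vo] += arr[z + (long)Z * y + ZY * x];
        cnt[vo] += 1.0;
      }
    }
  }
  NumericVector out(No);
  for (long i = 0; i < No; ++i) out[i] = cnt[i] > 0 ? acc[i] / cnt[i] : 0.0;
  out.attr("dim") = IntegerVector::create(Zo, Yo, Xo);
  return List::create(_["data"] = out,
                      _["dim"] = IntegerVector::create(Zo, Yo, Xo));
}

namespace {
inline double cubic_w(double t) {
  // Catmull-Rom
  double a = -0.5, at = std::fabs(t);
  if (at <= 1) return (a + 2) * at * at * at - (a + 3) * at * at + 1;
  if (at < 2) return a * at * at * at - 5 * a * at * at + 8 * a * at - 4 * a;
  return 0;
}
}  // namespace

// Per-z-plane bicubic (Catmull-Rom) resize in (y, x); nearest across z.
// [[Rcpp::export]]
NumericVector bicubic_resize_cpp(NumericVector arr, IntegerVector out_dim) {
  IntegerVector dim = arr.attr("dim");
  int Z = dim[0], Y = dim[1], X = dim[2];
  int Zo = out_dim[0], Yo = out_dim[1], Xo = out_dim[2];
  NumericVector out((long)Zo * Yo * Xo);
  double fy = (double)Y / Yo, fx = (double)X / Xo, fz = (double)Z / Zo;
  long ZY = (long)Z * Y;
  for (int xo = 0; xo < Xo; ++xo) {
    double sx = (xo + 0.5) * fx - 0.5;
    int x0 = (int)std::floor(sx);
    double tx = sx - x0;
    double wx[4];
    for (int i = 0; i < 4; ++i) wx[i] = cubic_w(tx - (i - 1));
    for (int yo = 0; yo < Yo; ++yo) {
      double sy = (yo + 0.5) * fy - 0.5;
      int y0 = (int)std::floor(sy);
      double ty = sy - y0;
      double wy[4];
      for (int i = 0; i < 4; ++i) wy[i] = cubic_w(ty - (i - 1));
      for (int zo = 0; zo < Zo; ++zo) {
        int zs = std::min(Z - 1, std::max(0, (int)((zo + 0.5) * fz)));
        double acc = 0;
        for (int i = 0; i < 4; ++i) {
          int xi = std::min(X - 1, std::max(0, x0 + i - 1));
          for (int j = 0; j < 4; ++j) {
            int yj = std::min(Y - 1, std::max(0, y0 + j - 1));
            acc += wx[i] * wy[j] * arr[zs + (long)Z * yj + ZY * xi];
          }
        }
        out[zo + (long)Zo * yo + (long)Zo * Yo * xo] = acc;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Zo, Yo, Xo);
  return out;
}

// Trilinear interpolation at continuous voxel-unit coordinates (physical
// position / spacing, so the volume spans [0, dim] and the center of voxel
// i is at i - 0.5). pts is N x 3 (z, y, x). Points outside get `fill`.
// [[Rcpp::export]]
NumericVector trilinear_sample_cpp(NumericVector arr, NumericMatrix pts,
                                   double fill) {
  IntegerVector dim = arr.attr("dim");
  int Z = dim[0], Y = dim[1], X = dim[2];
  int n = pts.nrow();
  NumericVector out(n);
  long ZY = (long)Z * Y;
  for (int i = 0; i < n; ++i) {
    // pts are continuous voxel-unit coordinates (physical position divided
    // by spacing, range [0, dim]); the center of 1-based voxel i sits at
    // i - 0.5, so u has integers at voxel centers after shifting by 0.5
    double uz = pts(i, 0) - 0.5, uy = pts(i, 1) - 0.5, ux = pts(i, 2) - 0.5;
    if (uz < -0.5 || uz > Z - 0.5 || uy < -0.5 || uy > Y - 0.5 ||
        ux < -0.5 || ux > X - 0.5) {
      out[i] = fill;
      continue;
    }
    int z0 = (int)std::floor(uz), y0 = (int)std::floor(uy),
        x0 = (int)std::floor(ux);
    double tz = uz - z0, ty = uy - y0, tx = ux - x0;
    double acc = 0;
    for (int dz = 0; dz < 2; ++dz)
      for (int dy = 0; dy < 2; ++dy)
        for (int dx = 0; dx < 2; ++dx) {
          int zi = std::min(Z - 1, std::max(0, z0 + dz));
          int yi = std::min(Y - 1, std::max(0, y0 + dy));
          int xi = std::min(X - 1, std::max(0, x0 + dx));
          double w = (dz ? tz : 1 - tz) * (dy ? ty : 1 - ty) *
                     (dx ? tx : 1 - tx);
          acc += w * arr[zi + (long)Z * yi + ZY * xi];
        }
    out[i] = acc;
  }
  return out;
}

// Render Gaussian blobs into an intensity volume and a binary label mask.
// centers_um: N x 3 (z,y,x) in micrometres; sigma_um, radius_um: per blob.
// [[Rcpp::export]]
List render_blobs_cpp(IntegerVector dim, NumericVector spacing,
                      NumericMatrix centers_um, NumericVector sigma_um,
                      NumericVector radius_um, double amplitude) {
  int Z = dim[0], Y = dim[1], X = dim[2];
  long N = (long)Z * Y * X;
  NumericVector intensity(N);
  LogicalVector mask(N);
  IntegerVector blob_vox(centers_um.nrow());
  long ZY = (long)Z * Y;
  for (int i = 0; i < centers_um.nrow(); ++i) {
    double cz = centers_um(i, 0), cy = centers_um(i, 1), cx = centers_um(i, 2);
    double rad = radius_um[i], sig = sigma_um[i];
    double ext = std::max(rad, 3.0 * sig);
    int z0 = std::max(0, (int)std::floor((cz - ext) / spacing[0] - 0.5));
    int z1 = std::min(Z - 1, (int)std::ceil((cz + ext) / spacing[0] + 0.5));
    int y0 = std::max(0, (int)std::floor((cy - ext) / spacing[1] - 0.5));
    int y1 = std::min(Y - 1, (int)std::ceil((cy + ext) / spacing[1] + 0.5));
    int x0 = std::max(0, (int)std::floor((cx - ext) / spacing[2] - 0.5));
    int x1 = std::min(X - 1, (int)std::ceil((cx + ext) / spacing[2] + 0.5));
    for (int x = x0; x <= x1; ++x) {
      double px = (x + 0.5) * spacing[2] - cx;
      for (int y = y0; y <= y1; ++y) {
        double py = (y + 0.5) * spacing[1] - cy;
        for (int z = z0; z <= z1; ++z) {
          double pz = (z + 0.5) * spacing[0] - cz;
          double r2 = px * px + py * py + pz * pz;
          long v = z + (long)Z * y + ZY * x;
          intensity[v] += amplitude * std::exp(-0.5 * r2 / (sig * sig));
          if (r2 <= rad * rad) { mask[v] = true; blob_vox[i] += 1; }
        }
      }
    }
    if (blob_vox[i] == 0) {
      // a blob smaller than the voxel half-diagonal still owns >= 1 voxel
      int zc = std::min(Z - 1, std::max(0, (int)(cz / spacing[0])));
      int yc = std::min(Y - 1, std::max(0, (int)(cy / spacing[1])));
      int xc = std::min(X - 1, std::max(0, (int)(cx / spacing[2])));
      long v = zc + (long)Z * yc + ZY * xc;
      if (!mask[v]) { mask[v] = true; blob_vox[i] = 1; }
    }
  }
  intensity.attr("dim") = dim;
  mask.attr("dim") = dim;
  return List::create(_["intensity"] = intensity, _["mask"] = mask,
                      _["blob_vox"] = blob_vox);
}

// Joint histogram with partial-volume (soft, linear) bin assignment.
// Both inputs are scaled to their own [min, max]; returns a bins x bins
// matrix of probabilities summing to 1.
// [[Rcpp::export]]
NumericMatrix soft_joint_hist_cpp(NumericVector a, NumericVector b,
                                  int bins) {
  int n = a.size();
  NumericMatrix pj(bins, bins);
  double amin = R_PosInf, amax = R_NegInf, bmin = R_PosInf, bmax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    amin = std::min(amin, a[i]); amax = std::max(amax, a[i]);
    bmin = std::min(bmin, b[i]); bmax = std::max(bmax, b[i]);
  }
  if (amax <= amin) amax = amin + 1;
  if (bmax <= bmin) bmax = bmin + 1;
  double asc = (bins - 1) / (amax - amin), bsc = (bins - 1) / (bmax - bmin);
  for (int i = 0; i < n; ++i) {
    double ua = (a[i] - amin) * asc, ub = (b[i] - bmin) * bsc;
    int ka = std::min((int)ua, bins - 2), kb = std::min((int)ub, bins - 2);
    double wa = ua - ka, wb = ub - kb;
    pj(ka, kb) += (1 - wa) * (1 - wb);
    pj(ka + 1, kb) += wa * (1 - wb);
    pj(ka, kb + 1) += (1 - wa) * wb;
    pj(ka + 1, kb + 1) += wa * wb;
  }
  for (int i = 0; i < bins * bins; ++i) pj[i] /= n;
  return pj;
}
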