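#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared-distance transform (lower envelope of parabolas), with sample
// spacing w so that distances come out in physical units.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 double w, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double w2 = w * w;
  int k = -1; // index of rightmost parabola in the envelope
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue; // infinite parabolas never enter the envelope
    double s = 0.0;
    while (k >= 0) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (s <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    z[k] = (k == 0) ? -INF : s;
    z[k + 1] = INF;
  }
  if (k < 0) { // no finite source anywhere on this line
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int idx = 0;
  for (int q = 0; q < n; ++q) {
    while (z[idx + 1] < q) ++idx;
    double dx = w * (q - v[idx]);
    d[q] = dx * dx + f[v[idx]];
  }
}

//' @keywords internal
// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericVector edt_sq_cpp(LogicalVector feature, IntegerVector dims,
                         NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (feature[i] == TRUE) ? 0.0 : INF;

  std::vector<double> f, d;
  // pass along x
  f.resize(nx); d.resize(nx);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      dt1d(f, d, spacing[0], nx);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)nx * j];
      dt1d(f, d, spacing[1], ny);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)nx * j] = d[j];
    }
  // pass along z
  f.resize(nz); d.resize(nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      R_xlen_t stride = (R_xlen_t)nx * ny;
      for (int k = 0; k < nz; ++k) f[k] = out[base + stride * k];
      dt1d(f, d, spacing[2], nz);
      for (int k = 0; k < nz; ++k) out[base + stride * k] = d[k];
    }
  return out;
}

// Resample a source volume through an affine map: for each target voxel with
// world position x, sample source at y = A x + t. method 0 = linear,
// 1 = nearest neighbour. Outside the source grid -> NA.
//' @keywords internal
// [[Rcpp::export(name = ".resample_affine_cpp")]]
NumericVector resample_affine_cpp(NumericVector src, IntegerVector sdim,
                                  NumericVector sspacing, NumericVector sorigin,
                                  NumericVector A, NumericVector tvec,
                                  IntegerVector tdim, NumericVector tspacing,
                                  NumericVector torigin, int method) {
  const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  const int tx = tdim[0], ty = tdim[1], tz = tdim[2];
  NumericVector out((R_xlen_t)tx * ty * tz);
  const double eps = 1e-9;
  R_xlen_t idx = 0;
  for (int k = 0; k < tz; ++k) {
    double wz = torigin[2] + k * tspacing[2];
    for (int j = 0; j < ty; ++j) {
      double wy = torigin[1] + j * tspacing[1];
      for (int i = 0; i < tx; ++i, ++idx) {
        double wx = torigin[0] + i * tspacing[0];
        double mx = A[0] * wx + A[3] * wy + A[6] * wz + tvec[0];
        double my = A[1] * wx + A[4] * wy + A[7] * wz + tvec[1];
        double mz = A[2] * wx + A[5] * wy + A[8] * wz + tvec[2];
        double ci = (mx - sorigin[0]) / sspacing[0];
        double cj = (my - sorigin[1]) / sspacing[1];
        double ck = (mz - sorigin[2]) / sspacing[2];
        if (method == 1) {
          int ri = (int)std::floor(ci + 0.5), rj = (int)std::floor(cj + 0.5),
              rk = (int)std::floor(ck + 0.5);
          if (ri < 0 || rj < 0 || rk < 0 || ri >= sx || rj >= sy || rk >= sz) {
            out[idx] = NA_REAL;
          } else {
            out[idx] = src[ri + (R_xlen_t)sx * (rj + (R_xlen_t)sy * rk)];
          }
        } else {
          // snap to grid within eps so exact-identity transforms are lossless
          double rci = std::floor(ci + 0.5);
          if (std::fabs(ci - rci) < eps) ci = rci;
          double rcj = std::floor(cj + 0.5);
          if (std::fabs(cj - rcj) < eps) cj = rcj;
          double rck = std::floor(ck + 0.5);
          if (std::fabs(ck - rck) < eps) ck = rck;
          if (ci < 0 || cj < 0 || ck < 0 || ci > sx - 1 || cj > sy - 1 ||
              ck > sz - 1) {
            out[idx] = NA_REAL;
            continue;
          }
          int i0 = (int)std::floor(ci), j0 = (int)std::floor(cj),
              k0 = (int)std::floor(ck);
          int i1 = std::min(i0 + 1, sx - 1), j1 = std::min(j0 + 1, sy - 1),
              k1 = std::min(k0 + 1, sz - 1);
          double fi = ci - i0, fj = cj - j0, fk = ck - k0;
          double acc = 0.0, wsum = 0.0;
          bool na = false;
          for (int dk = 0; dk <= 1 && !na; ++dk)
            for (int dj = 0; dj <= 1 && !na; ++dj)
              for (int di = 0; di <= 1 && !na; ++di) {
                double w = (di ? fi : 1 - fi) * (dj ? fj : 1 - fj) *
                           (dk ? fk : 1 - fk);
                if (w <= 0) continue;
                double v = src[(di ? i1 : i0) +
                               (R_xlen_t)sx * ((dj ? j1 : j0) +
                                               (R_xlen_t)sy * (dk ? k1 : k0))];
                if (ISNAN(v)) { na = true; break; }
                acc += w * v;
                wsum += w;
              }
          out[idx] = (na || wsum <= 0) ? NA_REAL : acc / wsum;
        }
      }
    }
  }
  return out;
}

// Mutual information of two equal-length vectors over their jointly finite
// entries, via a bins x bins joint histogram on fixed ranges.
//' @keywords internal
// [[Rcpp::export(name = ".mutual_information_cpp")]]
double mutual_information_cpp(NumericVector x, NumericVector y, int bins,
                              double xmin, double xmax, double ymin,
                              double ymax, int normalized) {
  std::vector<double> joint((size_t)bins * bins, 0.0);
  std::vector<double> px(bins, 0.0), py(bins, 0.0);
  double n = 0.0;
  const double xw = (xmax - xmin) / bins, yw = (ymax - ymin) / bins;
  if (xw <= 0 || yw <= 0) return NA_REAL;
  const R_xlen_t len = x.size();
  for (R_xlen_t i = 0; i < len; ++i) {
    double xv = x[i], yv = y[i];
    if (ISNAN(xv) || ISNAN(yv)) continue;
    int bx = (int)((xv - xmin) / xw);
    int by = (int)((yv - ymin) / yw);
    if (bx < 0) bx = 0; if (bx >= bins) bx = bins - 1;
    if (by < 0) by = 0; if (by >= bins) by = bins - 1;
    joint[bx + (size_t)bins * by] += 1.0;
    n += 1.0;
  }
  if (n < 2) return NA_REAL;
  for (int by = 0; by < bins; ++by)
    for (int bx = 0; bx < bins; ++bx) {
      double c = joint[bx + (size_t)bins * by];
      px[bx] += c;
      py[by] += c;
    }
  double hx = 0.0, hy = 0.0, hxy = 0.0;
  for (int b = 0; b < bins; ++b) {
    double p = px[b] / n;
    if (p > 0) hx -= p * std::log(p);
    p = py[b] / n;
    if (p > 0) hy -= p * std::log(p);
  }
  for (int by = 0; by < bins; ++by)
    for (int bx = 0; bx < bins; ++bx) {
      double pj = joint[bx + (size_t)bins * by] / n;
      if (pj > 0) hxy -= pj * std::log(pj);
    }
  if (normalized) {
    if (hxy <= 0) return NA_REAL;
    return (hx + hy) / hxy; // Studholme normalized MI, overlap-invariant
  }
  return hx + hy - hxy;
}
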