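#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Symmetric (half-sample) reflection: index -1 -> 0, -2 -> 1, n -> n-1, ...
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  if (i >= n) i = period - 1 - i;
  return i;
}

// Convolve a 3D array (column-major, dims d0 x d1 x d2) with a 1-D kernel
// along one axis, reflection boundary. Kernel is centred: radius r = (len-1)/2.
static void conv_axis(const double* in, double* out,
                      int d0, int d1, int d2,
                      const double* kern, int klen, int axis) {
  const int r = (klen - 1) / 2;
  const int n = (axis == 0) ? d0 : (axis == 1) ? d1 : d2;
  std::vector<double> line(n);
  if (axis == 0) {
    for (int k = 0; k < d2; ++k)
      for (int j = 0; j < d1; ++j) {
        const double* src = in + (size_t)(k * d1 + j) * d0;
        for (int i = 0; i < n; ++i) {
          double acc = 0.0;
          for (int t = 0; t < klen; ++t)
            acc += kern[t] * src[reflect_idx(i + t - r, n)];
          line[i] = acc;
        }
        double* dst = out + (size_t)(k * d1 + j) * d0;
        for (int i = 0; i < n; ++i) dst[i] = line[i];
      }
  } else if (axis == 1) {
    for (int k = 0; k < d2; ++k)
      for (int i = 0; i < d0; ++i) {
        const size_t base = (size_t)k * d1 * d0 + i;
        for (int j = 0; j < n; ++j) {
          double acc = 0.0;
          for (int t = 0; t < klen; ++t)
            acc += kern[t] * in[base + (size_t)reflect_idx(j + t - r, n) * d0];
          line[j] = acc;
        }
        for (int j = 0; j < n; ++j) out[base + (size_t)j * d0] = line[j];
      }
  } else {
    const size_t plane = (size_t)d0 * d1;
    for (int j = 0; j < d1; ++j)
      for (int i = 0; i < d0; ++i) {
        const size_t base = (size_t)j * d0 + i;
        for (int k = 0; k < n; ++k) {
          double acc = 0.0;
          for (int t = 0; t < klen; ++t)
            acc += kern[t] * in[base + (size_t)reflect_idx(k + t - r, n) * plane];
          line[k] = acc;
        }
        for (int k = 0; k < n; ++k) out[base + (size_t)k * plane] = line[k];
      }
  }
}

// [[Rcpp::export]]
NumericVector cpp_sep_conv3d(NumericVector vol, IntegerVector dims,
                             NumericVector kx, NumericVector ky,
                             NumericVector kz) {
  const int d0 = dims[0], d1 = dims[1], d2 = dims[2];
  NumericVector out(vol.size());
  std::vector<double> tmp(vol.size());
  conv_axis(vol.begin(), tmp.data(), d0, d1, d2, kx.begin(), kx.size(), 0);
  conv_axis(tmp.data(), out.begin(), d0, d1, d2, ky.begin(), ky.size(), 1);
  conv_axis(out.begin(), tmp.data(), d0, d1, d2, kz.begin(), kz.size(), 2);
  std::copy(tmp.begin(), tmp.end(), out.begin());
  out.attr("dim") = dims;
  return out;
}

// Eigenvalues of the symmetric 3x3 matrix
//   [ a d e ]
//   [ d b f ]
//   [ e f c ]
// per voxel, sorted by increasing absolute value (|l1| <= |l2| <= |l3|).
// Closed-form trigonometric solution.
// [[Rcpp::export]]
List cpp_sym3_eigen(NumericVector a, NumericVector b, NumericVector c,
                    NumericVector d, NumericVector e, NumericVector f) {
  const R_xlen_t n = a.size();
  NumericVector l1(n), l2(n), l3(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double A = a[i], B = b[i], C = c[i], D = d[i], E = e[i], F = f[i];
    double ev[3];
    const double p1 = D * D + E * E + F * F;
    if (p1 == 0.0) {
      ev[0] = A; ev[1] = B; ev[2] = C;
    } else {
      const double q = (A + B + C) / 3.0;
      const double p2 = (A - q) * (A - q) + (B - q) * (B - q) +
                        (C - q) * (C - q) + 2.0 * p1;
      const double p = std::sqrt(p2 / 6.0);
      // B = (A - q I) / p
      const double b11 = (A - q) / p, b22 = (B - q) / p, b33 = (C - q) / p;
      const double b12 = D / p, b13 = E / p, b23 = F / p;
      double detB = b11 * (b22 * b33 - b23 * b23) -
                    b12 * (b12 * b33 - b23 * b13) +
                    b13 * (b12 * b23 - b22 * b13);
      double r = detB / 2.0;
      if (r < -1.0) r = -1.0;
      if (r > 1.0) r = 1.0;
      const double phi = std::acos(r) / 3.0;
      ev[0] = q + 2.0 * p * std::cos(phi);
      ev[2] = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
      ev[1] = 3.0 * q - ev[0] - ev[2];
    }
    // sort by |.| ascending
    double x0 = ev[0], x1 = ev[1], x2 = ev[2], t;
    if (std::fabs(x0) > std::fabs(x1)) { t = x0; x0 = x1; x1 = t; }
    if (std::fabs(x1) > std::fabs(x2)) { t = x1; x1 = x2; x2 = t; }
    if (std::fabs(x0) > std::fabs(x1)) { t = x0; x0 = x1; x1 = t; }
    l1[i] = x0; l2[i] = x1; l3[i] = x2;
  }
  return List::create(_["l1"] = l1, _["l2"] = l2, _["l3"] = l3);
}

// 26-connectivity connected-component labeling of a logical 3D mask.
// Returns an integer array: 0 = background, 1..K = component labels.
// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dims) {
  const int d0 = dims[0], d1 = dims[1], d2 = dims[2];
  const R_xlen_t n = (R_xlen_t)d0 * d1 * d2;
  IntegerVector lab(n);
  std::fill(lab.begin(), lab.end(), 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t v = stack.back();
      stack.pop_back();
      const int i = (int)(v % d0);
      const int j = (int)((v / d0) % d1);
      const int k = (int)(v / ((R_xlen_t)d0 * d1));
      for (int dk = -1; dk <= 1; ++dk) {
        const int kk = k + dk;
        if (kk < 0 || kk >= d2) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          const int jj = j + dj;
          if (jj < 0 || jj >= d1) continue;
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            const int ii = i + di;
            if (ii < 0 || ii >= d0) continue;
            const R_xlen_t w = (R_xlen_t)kk * d0 * d1 + (R_xlen_t)jj * d0 + ii;
            if (mask[w] && lab[w] == 0) {
              lab[w] = next;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
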