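// Exact 3D Euclidean distance transform (Felzenszwalb & Huttenlocher
// lower-envelope-of-parabolas algorithm), plus a feature-transform variant
// that returns the linear index of the nearest site voxel.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const float FINF = std::numeric_limits<float>::infinity();

// 1D squared distance transform with label propagation.
// f: input squared values; lab: input labels (-1 where f == inf)
static void dt1d(const std::vector<float> &f, const std::vector<int> &lab,
                 int n, std::vector<float> &d, std::vector<int> &dl,
                 std::vector<int> &v, std::vector<float> &z) {
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == FINF) continue;
    if (k < 0) { k = 0; v[0] = q; z[0] = -FINF; z[1] = FINF; continue; }
    float s;
    while (true) {
      int p = v[k];
      s = ((f[q] + (float)q * q) - (f[p] + (float)p * p)) / (2.0f * (q - p));
      if (s <= z[k]) { --k; if (k < 0) break; } else break;
    }
    if (k < 0) { k = 0; v[0] = q; z[0] = -FINF; z[1] = FINF; }
    else { ++k; v[k] = q; z[k] = s; z[k + 1] = FINF; }
  }
  if (k < 0) { // no finite parabola in this line
    for (int q = 0; q < n; ++q) { d[q] = FINF; dl[q] = -1; }
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (z[j + 1] < (float)q) ++j;
    int p = v[j];
    d[q] = (float)(q - p) * (q - p) + f[p];
    dl[q] = lab[p];
  }
}

static void dt_axis(std::vector<float> &F, std::vector<int> &L, int n1, int n2,
                    int n3, int axis) {
  const int len = (axis == 0) ? n1 : (axis == 1) ? n2 : n3;
  const long stride = (axis == 0) ? 1L : (axis == 1) ? (long)n1 : (long)n1 * n2;
  const int u1 = (axis == 0) ? n2 : n1;
  const int u2 = (axis == 2) ? n2 : n3;
  std::vector<float> f(len), d(len), z(len + 1);
  std::vector<int> lab(len), dl(len), v(len);
  for (int b = 0; b < u2; ++b) {
    for (int a2 = 0; a2 < u1; ++a2) {
      long base;
      if (axis == 0) base = (long)n1 * (a2 + (long)n2 * b);
      else if (axis == 1) base = a2 + (long)n1 * n2 * b;
      else base = a2 + (long)n1 * b;
      for (int t = 0; t < len; ++t) {
        f[t] = F[base + stride * t];
        lab[t] = L[base + stride * t];
      }
      dt1d(f, lab, len, d, dl, v, z);
      for (int t = 0; t < len; ++t) {
        F[base + stride * t] = d[t];
        L[base + stride * t] = dl[t];
      }
    }
  }
}

// Distance (in voxels) from every voxel to the nearest zero voxel of `mask`.
// Voxels where mask == 0 get distance 0.
// [[Rcpp::export]]
NumericVector edt3d_cpp(IntegerVector mask, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const long N = (long)n1 * n2 * n3;
  std::vector<float> F(N);
  std::vector<int> L(N);
  for (long i = 0; i < N; ++i) {
    F[i] = mask[i] ? FINF : 0.0f;
    L[i] = mask[i] ? -1 : (int)i;
  }
  dt_axis(F, L, n1, n2, n3, 0);
  dt_axis(F, L, n1, n2, n3, 1);
  dt_axis(F, L, n1, n2, n3, 2);
  NumericVector out(N);
  for (long i = 0; i < N; ++i) out[i] = (F[i] == FINF) ? R_PosInf : std::sqrt((double)F[i]);
  out.attr("dim") = dims;
  return out;
}

// For every voxel, the 1-based linear index of the nearest site voxel
// (site = nonzero entry of `sites`).
// [[Rcpp::export]]
IntegerVector nearest_site_cpp(IntegerVector sites, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const long N = (long)n1 * n2 * n3;
  std::vector<float> F(N);
  std::vector<int> L(N);
  for (long i = 0; i < N; ++i) {
    F[i] = sites[i] ? 0.0f : FINF;
    L[i] = sites[i] ? (int)i : -1;
  }
  dt_axis(F, L, n1, n2, n3, 0);
  dt_axis(F, L, n1, n2, n3, 1);
  dt_axis(F, L, n1, n2, n3, 2);
  IntegerVector lab(N);
  for (long i = 0; i < N; ++i)
    lab[i] = (L[i] < 0) ? NA_INTEGER : L[i] + 1;
  lab.attr("dim") = dims;
  return lab;
}

// Hildebrand-style local thickness: every skeleton voxel s carries an
// inscribed-sphere radius r(s) (its EDT value); each mask voxel covered by a
// sphere takes the largest covering radius. Voxels left uncovered fall back
// to the nearest skeleton voxel's radius in R code.
// [[Rcpp::export]]
NumericVector paint_spheres_cpp(IntegerVector dims, IntegerVector skel_lin,
                                NumericVector skel_rad) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const long N = (long)n1 * n2 * n3;
  NumericVector out(N);
  for (int s = 0; s < skel_lin.size(); ++s) {
    long lin = (long)skel_lin[s] - 1;
    int i = (int)(lin % n1);
    int j = (int)((lin / n1) % n2);
    int k = (int)(lin / ((long)n1 * n2));
    double r = skel_rad[s];
    int ir = (int)std::floor(r);
    double r2 = r * r;
    int klo = std::max(0, k - ir), khi = std::min(n3 - 1, k + ir);
    for (int kk = klo; kk <= khi; ++kk) {
      double dz2 = (double)(kk - k) * (kk - k);
      int jr = (int)std::floor(std::sqrt(std::max(0.0, r2 - dz2)));
      int jlo = std::max(0, j - jr), jhi = std::min(n2 - 1, j + jr);
      for (int jj = jlo; jj <= jhi; ++jj) {
        double dyz2 = dz2 + (double)(jj - j) * (jj - j);
        int irx = (int)std::floor(std::sqrt(std::max(0.0, r2 - dyz2)));
        int ilo = std::max(0, i - irx), ihi = std::min(n1 - 1, i + irx);
        long base = (long)n1 * (jj + (long)n2 * kk);
        for (int ii = ilo; ii <= ihi; ++ii) {
          if (r > out[base + ii]) out[base + ii] = r;
        }
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}
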